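## Collective variables: switched coordination counts of the Hoogsteen
## hydrogen-bond network (Hb_core and its per-topology variants) and the
## guanine stacking density (pipi_core), plus COLVAR-dialect IO.
##
## Default switching parameters are calibrated on the idealised
## geometries so that one formed Hoogsteen bond or one stacked
## within-column guanine interface contributes ~1: a fully formed
## three-tetrad core scores Hb_core ~ 24 (two bonds per edge, four
## edges per tetrad, three tetrads) and pipi_core ~ 8 (four strand
## columns times two stacked interfaces).

#' Construct a switching function
#'
#' @param r0 switching radius, Angstrom.
#' @param d0 offset, Angstrom; distances <= d0 count fully.
#' @param n,m even rational exponents, m > n.
#' @return a [SwitchingFunction-class].
#' @export
switchingFunction <- function(r0 = 1.0, d0 = 0.0, n = 6L, m = 12L) {
  new("SwitchingFunction", r0 = r0, d0 = d0, n = as.integer(n),
      m = as.integer(m))
}

#' Default switching functions for the two CV families
#'
#' Hydrogen-bond coordination: d0 = 3.2, r0 = 0.5 (a donor-acceptor
#' pair at the ideal 2.8-3.1 Angstrom scores ~1; a pair stretched one
#' helical rise apart scores ~0).  Ring stacking: d0 = 4.0, r0 = 1.5
#' (a stacked within-column centroid pair at ~3.4-4.4 Angstrom scores
#' ~1).
#'
#' @name cv-defaults
#' @export
hbondSwitch <- function() switchingFunction(r0 = 0.5, d0 = 3.2)

#' @rdname cv-defaults
#' @export
stackingSwitch <- function() switchingFunction(r0 = 1.5, d0 = 4.0)

#' Evaluate a rational switching function
#'
#' \eqn{s(r) = (1 - x^n)/(1 - x^m)}, \eqn{x = (r - d0)/r0}; the
#' removable singularity at x = 1 is evaluated by its limit n/m.
#' Negative x (r < d0) is clamped to 1 so that fully formed contacts
#' saturate.
#'
#' @param r distances, Angstrom (vectorised).
#' @param sf a [SwitchingFunction-class].
#' @return values in (0, 1].
#' @export
switchValue <- function(r, sf) {
  stopifnot(all(r >= 0))
  x <- (r - sf@d0) / sf@r0
  s <- numeric(length(x))
  s[x <= 0] <- 1
  sing <- x > 0 & abs(x - 1) < 1e-10
  s[sing] <- sf@n / sf@m
  reg <- x > 0 & !sing
  xr <- x[reg]
  s[reg] <- (1 - xr^sf@n) / (1 - xr^sf@m)
  s
}

#' Build a coordination CV specification
#'
#' @param name CV name.
#' @param pairs two-column integer matrix of (donor, acceptor) atom
#'   indices.
#' @param switch a [SwitchingFunction-class]; default [hbondSwitch()].
#' @return a [CVSpec-class].
#' @export
coordinationSpec <- function(name, pairs, switch = hbondSwitch()) {
  new("CVSpec", name = name, kind = "coordination",
      pairs = matrix(as.integer(pairs), ncol = 2), switch = switch)
}

#' Build a pi-pi stacking CV specification
#'
#' The CV sums the switched centroid-centroid distances of the listed
#' ring pairs.  For a G-core the listed pairs are the consecutive
#' within-column guanine neighbours, so the native three-tetrad stem
#' scores ~8 stacked interfaces; cross-column diagonals are not
#' counted.
#'
#' @param name CV name.
#' @param ringGroups list of integer vectors of ring heavy-atom indices.
#' @param ringPairs two-column matrix of indices into \code{ringGroups};
#'   if missing, all i < j pairs are used.
#' @param switch a [SwitchingFunction-class]; default [stackingSwitch()].
#' @return a [CVSpec-class].
#' @export
pipiSpec <- function(name, ringGroups, ringPairs = NULL,
                     switch = stackingSwitch()) {
  if (is.null(ringPairs)) {
    ij <- which(upper.tri(diag(length(ringGroups))), arr.ind = TRUE)
    ringPairs <- ij
  }
  new("CVSpec", name = name, kind = "pipi",
      ringGroups = lapply(ringGroups, as.integer),
      ringPairs = matrix(as.integer(ringPairs), ncol = 2),
      switch = switch)
}

#' Build an RMSD CV specification
#'
#' Superposed RMSD of the indexed atoms against reference coordinates
#' (e.g. the G-core base heavy atoms against the crystallographic
#' native core).
#'
#' @param name CV name.
#' @param indices integer atom indices into the evaluated frames.
#' @param refCoords matrix of reference coordinates, same count.
#' @return a [CVSpec-class].
#' @export
rmsdSpec <- function(name, indices, refCoords) {
  stopifnot(length(indices) == nrow(refCoords))
  new("CVSpec", name = name, kind = "rmsd",
      refIndices = as.integer(indices),
      refCoords = as.matrix(refCoords))
}

.pair_distances <- function(m, pairs) {
  d <- m[pairs[, 1], , drop = FALSE] - m[pairs[, 2], , drop = FALSE]
  sqrt(rowSums(d^2))
}

#' Evaluate a coordination CV on one frame
#'
#' Sum of switched donor-acceptor distances over the spec's pair list.
#'
#' @param x a [G4Structure-class] or coordinate matrix.
#' @param spec a coordination [CVSpec-class].
#' @return non-negative scalar.
#' @export
coordinationCV <- function(x, spec) {
  stopifnot(spec@kind == "coordination")
  m <- .as_coord_matrix(x)
  if (max(spec@pairs) > nrow(m))
    stop("coordinationCV: pair index ", max(spec@pairs),
         " outside structure (", nrow(m), " atoms)", call. = FALSE)
  sum(switchValue(.pair_distances(m, spec@pairs), spec@switch))
}

#' Evaluate the pi-pi stacking CV on one frame
#'
#' @param x a [G4Structure-class] or coordinate matrix.
#' @param spec a pipi [CVSpec-class].
#' @return non-negative scalar.
#' @export
pipiCore <- function(x, spec) {
  stopifnot(spec@kind == "pipi")
  m <- .as_coord_matrix(x)
  cents <- t(vapply(spec@ringGroups,
                    function(g) colMeans(m[g, , drop = FALSE]),
                    numeric(3)))
  if (nrow(spec@ringPairs) == 0) return(0)
  sum(switchValue(.pair_distances(cents, spec@ringPairs), spec@switch))
}

#' Evaluate any CV on one frame
#'
#' @param x coordinates or structure.
#' @param spec a [CVSpec-class].
#' @return scalar CV value.
#' @export
evalCV <- function(x, spec) {
  switch(spec@kind,
         coordination = coordinationCV(x, spec),
         pipi = pipiCore(x, spec),
         rmsd = {
           m <- .as_coord_matrix(x, spec@refIndices)
           superpose(m, spec@refCoords)$rmsd
         },
         stop("unknown CV kind: ", spec@kind))
}

#' CV time series over a trajectory
#'
#' @param traj a [G4Trajectory-class].
#' @param specs list of [CVSpec-class] (possibly empty).
#' @return data.frame with \code{time} plus one column per CV, a
#'   COLVAR-style table writable with [writeColvar()].
#' @export
cvSeries <- function(traj, specs) {
  out <- data.frame(time = traj@times)
  for (spec in specs) {
    vals <- vapply(seq_len(nFrames(traj)), function(k) {
      tryCatch(evalCV(traj@coords[, , k], spec),
               error = function(e)
                 stop("cvSeries: frame ", k, ": ", conditionMessage(e),
                      call. = FALSE))
    }, 0.0)
    out[[spec@name]] <- vals
  }
  out
}

#' Write a COLVAR-dialect table
#'
#' First line \code{#! FIELDS time <names...>}, whitespace-separated
#' numeric rows.
#'
#' @param table data.frame whose first column is \code{time}.
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeColvar <- function(table, path) {
  stopifnot(names(table)[1] == "time")
  hdr <- paste("#! FIELDS", paste(names(table), collapse = " "))
  rows <- do.call(paste, c(lapply(table, function(v)
    sprintf("%.10g", v)), sep = " "))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read a COLVAR-dialect table
#'
#' @param path file written in the \code{#! FIELDS} dialect.
#' @return data.frame with the named columns.
#' @export
readColvar <- function(path) {
  first <- readLines(path, n = 1)
  if (!grepl("^#!\\s*FIELDS", first))
    stop("parse error: ", path, " has no '#! FIELDS' header",
         call. = FALSE)
  fields <- strsplit(sub("^#!\\s*FIELDS\\s+", "", first), "\\s+")[[1]]
  df <- read.table(path, comment.char = "#", col.names = fields,
                   colClasses = "numeric")
  if (nrow(df) && any(diff(df$time) <= 0) && length(df$time) > 1)
    warning("times in ", path, " are not strictly increasing")
  df
}
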