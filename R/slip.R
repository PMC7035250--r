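## Strand-slipped two-tetrad topologies of the parallel G-quadruplex.
##
## The native three-tetrad core is a 4 x 3 grid: four strand columns
## (G-triplets) by three planes.  A vertical slip moves one column's
## guanines one plane towards 3' ("d") or 5' ("u"); planes left with
## four members are G-tetrads, with three a G-triad, and guanines
## pushed past the core ends are unpaired.

#' Default strand layout of the 22-nt human telomeric parallel G4
#'
#' Four G-triplet columns, residues 5'->3' within each column.
#'
#' @return list of four integer vectors.
#' @export
defaultStrandLayout <- function() {
  list(c(2L, 3L, 4L), c(8L, 9L, 10L), c(14L, 15L, 16L),
       c(20L, 21L, 22L))
}

#' Parse or build a slip code
#'
#' \code{"native"} or digits + direction letter, e.g. \code{"2d"},
#' \code{"3u"}, \code{"24d"} (both named columns slip down).  Mixed
#' directions use digit-letter pairs, e.g. \code{"2d3u"}.
#'
#' @param label code string, or \code{moves} given directly.
#' @param moves optional data.frame with columns \code{column},
#'   \code{dir}.
#' @return a [SlipCode-class].
#' @export
slipCode <- function(label, moves = NULL) {
  if (is(label, "SlipCode")) return(label)
  if (is.null(moves)) {
    if (identical(label, "native")) {
      moves <- data.frame(column = integer(), dir = character())
    } else if (grepl("^[1-4]+[ud]$", label)) {
      cols <- as.integer(strsplit(sub("[ud]$", "", label), "")[[1]])
      moves <- data.frame(column = cols,
                          dir = rep(sub("^[1-4]+", "", label),
                                    length(cols)))
    } else if (grepl("^([1-4][ud])+$", label)) {
      parts <- regmatches(label, gregexpr("[1-4][ud]", label))[[1]]
      moves <- data.frame(column = as.integer(substr(parts, 1, 1)),
                          dir = substr(parts, 2, 2))
    } else {
      stop("unknown slip code: '", label, "'", call. = FALSE)
    }
  }
  new("SlipCode", label = label, moves = moves)
}

#' Apply a vertical slip to the strand layout
#'
#' A "d" move shifts a column's guanines one plane towards 3' (the top
#' guanine leaves the top plane, the bottom one exits the core); "u" is
#' the mirror image.  Planes with four members are tetrads, with three
#' triads (tagged by which end of the core they sit at); everything
#' else is unpaired.
#'
#' @param layout strand layout (list of 4 columns of 3 residues),
#'   default [defaultStrandLayout()].
#' @param code a [SlipCode-class] or code string.
#' @return a [TetradComposition-class].
#' @export
applySlip <- function(layout = defaultStrandLayout(), code = "native") {
  code <- slipCode(code)
  ncol <- length(layout)
  stopifnot(ncol >= 2, ncol <= 4, all(lengths(layout) == 3))
  nplane <- 3L
  shift <- integer(ncol)
  if (nrow(code@moves)) {
    if (any(code@moves$column > ncol))
      stop("slip code names a column outside the layout", call. = FALSE)
    shift[code@moves$column] <- ifelse(code@moves$dir == "d", 1L, -1L)
  }
  ## plane occupied by residue j of column c: j + shift[c]
  plane_of <- lapply(seq_len(ncol), function(c) seq_len(nplane) + shift[c])
  planes <- sort(unique(unlist(plane_of)))
  tetrads <- list(); triads <- list(); ends <- character()
  tricols <- list(); unp <- integer()
  for (p in planes) {
    members <- integer(); cols <- integer()
    for (c in seq_len(ncol)) {
      j <- which(plane_of[[c]] == p)
      if (length(j)) { members <- c(members, layout[[c]][j]); cols <- c(cols, c) }
    }
    if (p < 1 || p > nplane) {
      unp <- c(unp, members)
    } else if (length(members) == 4) {
      tetrads[[length(tetrads) + 1]] <- members
    } else if (length(members) == 3) {
      triads[[length(triads) + 1]] <- members
      tricols[[length(tricols) + 1]] <- cols
      ends <- c(ends, if (p <= nplane / 2 + 0.5) "5'" else "3'")
    } else {
      unp <- c(unp, members)
    }
  }
  new("TetradComposition", tetrads = tetrads, triads = triads,
      triadEnds = ends, triadColumns = tricols, unpaired = unp)
}

.comp_key <- function(comp) {
  paste(c(vapply(comp@tetrads, function(t) paste(sort(t), collapse = ","),
                 ""),
          "|",
          vapply(comp@triads, function(t) paste(sort(t), collapse = ","),
                 "")),
        collapse = ";")
}

#' Enumerate slipped topologies retaining two full tetrads
#'
#' All single slips (4 columns x u/d), plus double slips.  By default
#' doubles are restricted to pairs of same-direction "d" moves (the
#' only doubles observed for this fold); \code{full_doubles = TRUE}
#' opens the whole two-move space.  Compositions with fewer than two
#' full tetrad planes are dropped; duplicates (by composition) are
#' removed.  Order is deterministic: singles 5'->3' (d before u), then
#' doubles.
#'
#' @param layout strand layout.
#' @param max_simultaneous_moves 1 or 2.
#' @param full_doubles also enumerate u/u and mixed-direction doubles.
#' @return named list of [TetradComposition-class], names = slip codes.
#' @export
enumerateTopologies <- function(layout = defaultStrandLayout(),
                                max_simultaneous_moves = 1,
                                full_doubles = FALSE) {
  stopifnot(max_simultaneous_moves %in% 1:2)
  labels <- character()
  for (c in seq_along(layout)) for (dir in c("d", "u"))
    labels <- c(labels, paste0(c, dir))
  if (max_simultaneous_moves == 2) {
    for (c1 in 1:3) for (c2 in (c1 + 1):4) {
      if (full_doubles) {
        for (d1 in c("d", "u")) for (d2 in c("d", "u")) {
          labels <- c(labels, if (d1 == d2) paste0(c1, c2, d1)
                      else paste0(c1, d1, c2, d2))
        }
      } else {
        labels <- c(labels, paste0(c1, c2, "d"))
      }
    }
  }
  out <- list(); seen <- character()
  for (lb in labels) {
    comp <- tryCatch(applySlip(layout, lb), error = function(e) NULL)
    if (is.null(comp)) next
    if (length(comp@tetrads) < 2) next
    key <- .comp_key(comp)
    if (key %in% seen) next
    seen <- c(seen, key)
    out[[lb]] <- comp
  }
  out
}

.atom_index <- function(structure, resid, name) {
  a <- structure@atoms
  i <- which(a$resid == resid & a$name == name)
  if (!length(i))
    stop("structure is missing atom ", name, " of residue ", resid,
         call. = FALSE)
  i[1]
}

#' Hoogsteen donor-acceptor pair list for a composition
#'
#' For each tetrad the four cyclic edges (in strand-column order)
#' contribute the Hoogsteen donor-acceptor pairs; with
#' \code{both_bonds} each edge counts two hydrogen bonds
#' (N1(H1)->O6 and N2(H21)->N7, heavy-atom distances), otherwise only
#' N1->O6.  Triad edges (the open-form pattern, consecutive columns
#' only) are added when \code{include_triads}.
#'
#' @param comp a [TetradComposition-class].
#' @param structure a [G4Structure-class] with the core guanines.
#' @param include_triads also list the triad edges.
#' @param both_bonds two bonds per Hoogsteen edge (default) or one.
#' @return two-column integer matrix of (donor, acceptor) atom indices.
#' @export
hoogsteenPairs <- function(comp, structure, include_triads = FALSE,
                           both_bonds = TRUE) {
  pairs <- matrix(integer(), 0, 2)
  edge <- function(r_don, r_acc) {
    p <- rbind(c(.atom_index(structure, r_don, "N1"),
                 .atom_index(structure, r_acc, "O6")))
    if (both_bonds)
      p <- rbind(p, c(.atom_index(structure, r_don, "N2"),
                      .atom_index(structure, r_acc, "N7")))
    p
  }
  for (t in comp@tetrads) {
    for (i in 1:4)
      pairs <- rbind(pairs, edge(t[i], t[if (i == 4) 1 else i + 1]))
  }
  if (include_triads) {
    for (k in seq_along(comp@triads)) {
      t <- comp@triads[[k]]; cols <- comp@triadColumns[[k]]
      for (i in seq_along(t)) {
        j <- which(cols == (cols[i] %% 4) + 1)
        if (length(j)) pairs <- rbind(pairs, edge(t[i], t[j]))
      }
    }
  }
  pairs
}

#' Per-topology Hb_core CV specs
#'
#' Builds the coordination CV of the native composition plus every
#' enumerated slipped composition, with pair lists generated from the
#' topology (not hard-coded).
#'
#' @param structure topology structure holding the core guanines.
#' @param layout strand layout.
#' @param max_simultaneous_moves passed to [enumerateTopologies()].
#' @param switch switching function, default [hbondSwitch()].
#' @param both_bonds two H-bonds per Hoogsteen edge (default) or one.
#' @return named list of coordination [CVSpec-class]; first element is
#'   \code{"native"}.
#' @export
topologyCVSpecs <- function(structure, layout = defaultStrandLayout(),
                            max_simultaneous_moves = 2,
                            switch = hbondSwitch(), both_bonds = TRUE) {
  comps <- c(list(native = applySlip(layout, "native")),
             enumerateTopologies(layout, max_simultaneous_moves))
  lapply(stats::setNames(names(comps), names(comps)), function(nm)
    coordinationSpec(paste0("Hb_core_", nm),
                     hoogsteenPairs(comps[[nm]], structure,
                                    both_bonds = both_bonds),
                     switch = switch))
}

#' Classify one frame into a slipped topology
#'
#' Flow rules on the normalised Hoogsteen fractions
#' \eqn{f_X = Hb_{core,X} / max_X} (max = pair count, each fully
#' formed bond contributing ~1): a frame is \code{A-like} when the
#' native network is mostly intact (\eqn{f_{native} \ge t_{high}}); a
#' slipped label X is assigned when its network is mostly formed
#' (\eqn{f_X \ge t_{slip}}) and beats the slipped runner-up by at
#' least \code{t_margin}; frames with a partially intact native
#' network are transition-state-like (\code{TS}); anything else is
#' \code{unassigned}.  Ties fall through towards \code{unassigned}.
#'
#' The native gate is stricter than the slipped gate because a frame
#' part-way through a slip retains a sizeable fraction of the native
#' network (the shared tetrad edges) while the winning slipped
#' network is still completing; symmetric gates misread late
#' transition frames as native-like.
#'
#' @param x frame coordinates or [G4Structure-class].
#' @param specs named list from [topologyCVSpecs()] (must contain
#'   \code{"native"}).
#' @param t_high,t_slip,t_low,t_margin flow thresholds (defaults 0.80,
#'   0.70, 0.40, 0.05).
#' @return list with \code{label} and \code{scores} (named fractions).
#' @export
classifyFrame <- function(x, specs, t_high = 0.80, t_slip = 0.70,
                          t_low = 0.40, t_margin = 0.05) {
  if (!"native" %in% names(specs))
    stop("classifyFrame: specs must include a 'native' entry",
         call. = FALSE)
  f <- vapply(specs, function(sp)
    coordinationCV(x, sp) / nrow(sp@pairs), 0.0)
  label <- "unassigned"
  slipped <- f[names(f) != "native"]
  if (f[["native"]] >= t_high) {
    label <- "A-like"
  } else if (length(slipped)) {
    ord <- sort(slipped, decreasing = TRUE)
    if (ord[1] >= t_slip &&
        (length(ord) == 1 || ord[1] - ord[2] >= t_margin)) {
      label <- names(ord)[1]
    } else if (f[["native"]] >= t_low) {
      label <- "TS"
    }
  } else if (f[["native"]] >= t_low) {
    label <- "TS"
  }
  list(label = label, scores = f)
}

#' Classify every frame of a trajectory
#'
#' @param traj a [G4Trajectory-class].
#' @param specs named list from [topologyCVSpecs()].
#' @param ... thresholds passed to [classifyFrame()].
#' @return data.frame with \code{time_ps}, \code{label} and one
#'   \code{f_<topology>} column per spec.
#' @export
classifyTrajectory <- function(traj, specs, ...) {
  rows <- lapply(seq_len(nFrames(traj)), function(k)
    classifyFrame(traj@coords[, , k], specs, ...))
  sc <- t(vapply(rows, function(r) r$scores,
                 numeric(length(specs))))
  colnames(sc) <- paste0("f_", names(specs))
  data.frame(time_ps = traj@times,
             label = vapply(rows, function(r) r$label, ""),
             sc, check.names = FALSE)
}

#' Classify a G-triad as open, closed or absent
#'
#' An \emph{open} triad keeps the canonical Hoogsteen edge pattern
#' (N1->O6 and N2->N7 along consecutive columns) and coordinates a
#' cation near its O6 centroid; a \emph{closed} triad is hydrogen
#' bonded through rearranged (non-canonical) G:G edges, or canonical
#' edges with no coordinating cation; \code{none} means the three
#' guanines are not mutually within hydrogen-bonding reach.
#'
#' @param structure frame as a [G4Structure-class] (cations read from
#'   resname \code{"K"}).
#' @param triad integer(3) residue numbers.
#' @param cutoff_hb heavy-atom H-bond cutoff, Angstrom (default 3.5).
#' @param cutoff_cation cation-to-O6-centroid cutoff, Angstrom
#'   (default 4.0).
#' @return \code{"open"}, \code{"closed"} or \code{"none"}.
#' @export
classifyTriadForm <- function(structure, triad, cutoff_hb = 3.5,
                              cutoff_cation = 4.0) {
  m <- coords(structure)
  at <- function(r, nm) m[.atom_index(structure, r, nm), ]
  dst <- function(p, q) sqrt(sum((p - q)^2))
  n_canon <- 0L; n_edges <- 0L
  combs <- utils::combn(triad, 2)
  for (k in seq_len(ncol(combs))) {
    ri <- combs[1, k]; rj <- combs[2, k]
    hb <- FALSE; canon <- FALSE
    for (ord in list(c(ri, rj), c(rj, ri))) {
      d_n1o6 <- dst(at(ord[1], "N1"), at(ord[2], "O6"))
      d_n2n7 <- dst(at(ord[1], "N2"), at(ord[2], "N7"))
      d_n2o6 <- dst(at(ord[1], "N2"), at(ord[2], "O6"))
      d_n1n7 <- dst(at(ord[1], "N1"), at(ord[2], "N7"))
      if (d_n1o6 <= cutoff_hb && d_n2n7 <= cutoff_hb) canon <- TRUE
      if (min(d_n1o6, d_n2n7, d_n2o6, d_n1n7) <= cutoff_hb) hb <- TRUE
    }
    n_edges <- n_edges + hb
    n_canon <- n_canon + canon
  }
  if (n_edges < 2) return("none")
  a <- structure@atoms
  kat <- which(a$resname == "K" | (a$element == "K" & a$name == "K"))
  o6 <- t(vapply(triad, function(r) at(r, "O6"), numeric(3)))
  cent <- colMeans(o6)
  has_cation <- length(kat) > 0 &&
    any(sqrt(colSums((t(m[kat, , drop = FALSE]) - cent)^2)) <=
          cutoff_cation)
  if (n_canon >= 2 && has_cation) "open" else "closed"
}
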