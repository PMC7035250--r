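## Well-tempered metadynamics: hill bookkeeping, wall restraints and the
## overdamped Langevin sampler on analytic CV-space model potentials.

#' Well-tempered metadynamics parameters
#'
#' Defaults: initial Gaussian height 2.48 kJ/mol deposited every 1 ps,
#' bias factor 20, Gaussian widths (0.2, 0.5) for the hydrogen-bond and
#' stacking CVs, kT = 2.494 kJ/mol (300 K).
#'
#' @param w0 initial hill height, kJ/mol.
#' @param pace deposition stride, ps.
#' @param gamma bias factor, > 1.
#' @param sigma per-CV Gaussian widths.
#' @param kT thermal energy, kJ/mol.
#' @return a [WTMetaDParams-class].
#' @export
wtMetaDParams <- function(w0 = 2.48, pace = 1, gamma = 20,
                          sigma = c(0.2, 0.5), kT = 2.494) {
  new("WTMetaDParams", w0 = w0, pace = pace, gamma = gamma,
      sigma = sigma, kT = kT)
}

#' Empty bias state
#'
#' @param d number of biased CVs.
#' @return a [BiasState-class] with no hills.
#' @export
biasState <- function(d = 1L) {
  new("BiasState", d = as.integer(d),
      hills = matrix(numeric(), 0, 2 * d + 2))
}

#' Well-tempered hill height
#'
#' \eqn{W_0 \exp(-V / ((\gamma - 1) k T))}: the height of the next
#' Gaussian given the bias already accumulated at the deposition point.
#' As \eqn{\gamma \to \infty} heights stay at \eqn{W_0} (standard
#' metadynamics limit).
#'
#' @param V_current bias at the deposition point, kJ/mol (>= 0).
#' @param p a [WTMetaDParams-class].
#' @return height in kJ/mol.
#' @export
hillHeight <- function(V_current, p) {
  stopifnot(all(V_current >= -1e-9))
  p@w0 * exp(-V_current / ((p@gamma - 1) * p@kT))
}

#' Bias potential and gradient at a point
#'
#' Direct summation over all deposited Gaussians (the reference path;
#' the engine's grid cache agrees with this at its nodes to well below
#' 1e-6 kJ/mol).
#'
#' @param state a [BiasState-class].
#' @param s CV point (length d) or n x d matrix of points.
#' @return list with \code{value} (numeric) and \code{gradient}
#'   (n x d matrix).
#' @export
biasAt <- function(state, s) {
  d <- state@d
  S <- if (is.matrix(s)) s else matrix(s, ncol = d)
  h <- state@hills
  val <- numeric(nrow(S))
  grad <- matrix(0, nrow(S), d)
  if (nrow(h)) {
    for (k in seq_len(nrow(h))) {
      cen <- h[k, 2:(1 + d)]
      sig <- h[k, (2 + d):(1 + 2 * d)]
      hk <- h[k, 2 * d + 2]
      z <- sweep(S, 2, cen)
      g <- hk * exp(-rowSums(sweep(z^2, 2, 2 * sig^2, "/")))
      val <- val + g
      grad <- grad - g * sweep(z, 2, sig^2, "/")
    }
  }
  list(value = val, gradient = grad)
}

#' Deposit one well-tempered hill
#'
#' Appends a Gaussian centred at \code{s} with height
#' \code{hillHeight(biasAt(state, s), p)} and widths \code{p@sigma}.
#'
#' @param state a [BiasState-class].
#' @param s CV point, length d.
#' @param t deposition time, ps; must exceed the last hill time.
#' @param p a [WTMetaDParams-class].
#' @return the updated [BiasState-class].
#' @export
depositHill <- function(state, s, t, p) {
  h <- state@hills
  if (nrow(h) && t <= h[nrow(h), 1])
    stop("depositHill: hill time ", t, " not after last hill time ",
         h[nrow(h), 1], call. = FALSE)
  if (length(s) != state@d)
    stop("depositHill: point has wrong dimension", call. = FALSE)
  sig <- rep_len(p@sigma, state@d)
  V <- biasAt(state, s)$value
  state@hills <- rbind(h, c(t, s, sig, hillHeight(V, p)))
  if (length(state@gridNodes))
    state@gridValues <- state@gridValues +
      .hill_on_grid(state@gridNodes, s, sig, hillHeight(V, p))
  state
}

.hill_on_grid <- function(nodes, cen, sig, height, trunc = 6) {
  gl <- lapply(seq_along(nodes), function(i) {
    z <- (nodes[[i]] - cen[i]) / sig[i]
    e <- exp(-z^2 / 2)
    e[abs(z) > trunc] <- 0
    e
  })
  if (length(gl) == 1) height * gl[[1]] else height * outer(gl[[1]], gl[[2]])
}

#' Attach (or rebuild) a grid cache to a bias state
#'
#' Caches the summed bias at regular grid nodes; hills are truncated at
#' 6 sigma (an error below 1e-7 kJ/mol at default heights).
#'
#' @param state a [BiasState-class].
#' @param nodes list of node-position vectors, one per CV.
#' @return the state with cache attached.
#' @export
attachBiasGrid <- function(state, nodes) {
  stopifnot(length(nodes) == state@d)
  dims <- lengths(nodes)
  vals <- array(0, dims)
  h <- state@hills
  d <- state@d
  for (k in seq_len(nrow(h)))
    vals <- vals + .hill_on_grid(nodes, h[k, 2:(1 + d)],
                                 h[k, (2 + d):(1 + 2 * d)],
                                 h[k, 2 * d + 2])
  state@gridNodes <- nodes
  state@gridValues <- vals
  state
}

#' Lower wall restraint constructor
#'
#' @param cv index of the restrained CV.
#' @param threshold wall position.
#' @param kappa force constant, kJ/mol per unit^exp (default 500).
#' @param exp exponent >= 2 (default 2).
#' @return a [WallRestraint-class].
#' @export
wallRestraint <- function(cv, threshold, kappa = 500, exp = 2L) {
  new("WallRestraint", cv = as.integer(cv), threshold = threshold,
      side = "lower", kappa = kappa, exp = as.integer(exp))
}

#' Wall restraint energy and gradient
#'
#' Zero at or above the threshold; \eqn{\kappa (t - s)^{exp}} below it.
#'
#' @param s CV values (vectorised) of the restrained coordinate.
#' @param wall a [WallRestraint-class].
#' @return list with \code{value} and \code{gradient} (dV/ds).
#' @export
wallEnergy <- function(s, wall) {
  gap <- pmax(0, wall@threshold - s)
  list(value = wall@kappa * gap^wall@exp,
       gradient = -wall@kappa * wall@exp * gap^(wall@exp - 1))
}

#' Run overdamped Langevin dynamics under a well-tempered bias
#'
#' Samples the CV-space model potential with position Langevin dynamics
#' (\eqn{ds = -\nabla U dt / \zeta + \sqrt{2 kT dt / \zeta}\,\xi}),
#' depositing well-tempered Gaussians every \code{pace} ps, with
#' optional lower-wall restraints.  The bias is accumulated on a grid
#' (exact at the nodes, linearly interpolated between them) and the
#' walker reflects at the grid edges.  Fully reproducible for a given
#' seed.
#'
#' @param potential a [ModelPotential-class].
#' @param p a [WTMetaDParams-class] (use \code{w0 = 0} for an unbiased
#'   run; no hills are then deposited).
#' @param walls list of [WallRestraint-class] (may be empty).
#' @param n_steps number of integration steps.
#' @param dt time step, ps.
#' @param friction Langevin friction \eqn{\zeta}, kJ/mol ps / unit^2.
#' @param s0 starting point (length d).
#' @param grid list per CV of \code{c(min, max, n_nodes)}.
#' @param seed integer seed (applied with \code{set.seed}).
#' @param out_stride record every this many steps.
#' @return list with \code{colvar} (data.frame time, cv values,
#'   instantaneous bias), \code{bias} (a [BiasState-class] with the
#'   engine's grid cache attached), and \code{gridNodes}.
#' @export
runLangevinWTMetaD <- function(potential, p, walls = list(),
                               n_steps, dt, friction = 1,
                               s0 = NULL, grid = NULL, seed = 1,
                               out_stride = 10) {
  d <- potential@d
  if (is.null(s0)) s0 <- rep(0, d)
  if (is.null(grid))
    grid <- rep(list(c(-3, 3, 601)), d)
  stopifnot(length(s0) == d, length(grid) == d)
  gmin <- vapply(grid, `[`, 0, 1)
  gmax <- vapply(grid, `[`, 0, 2)
  gn <- vapply(grid, function(g) as.integer(g[3]), 0L)
  wallm <- if (length(walls))
    t(vapply(walls, function(w)
      c(w@cv, w@threshold, w@kappa, w@exp), numeric(4)))
  else matrix(numeric(), 0, 4)
  pace_steps <- max(1L, as.integer(round(p@pace / dt)))
  if (!is.null(seed)) set.seed(seed)
  res <- cpp_run_wtmetad(potential@cppId, potential@cppParams,
                         as.numeric(s0), n_steps, dt, friction, p@kT,
                         p@w0, rep_len(p@sigma, d), p@gamma, pace_steps,
                         as.integer(out_stride), gmin, gmax, gn, wallm)
  colvar <- as.data.frame(res$colvar)
  names(colvar) <- c("time", paste0("cv", seq_len(d)), "bias")
  hills <- res$hills
  state <- new("BiasState", d = as.integer(d), hills = hills,
               gridNodes = lapply(seq_len(d), function(i)
                 seq(gmin[i], gmax[i], length.out = gn[i])),
               gridValues = if (d == 1) array(res$grid, gn)
                            else array(res$grid, gn))
  list(colvar = colvar, bias = state, gridNodes = state@gridNodes)
}

#' Write hills in the HILLS dialect
#'
#' Header \code{#! FIELDS time <centers> <sigmas> height biasf};
#' the biasf column repeats the bias factor.
#'
#' @param state a [BiasState-class].
#' @param path output file.
#' @param cv_names CV names (default cv1, cv2, ...).
#' @param gamma bias factor written in the biasf column.
#' @return the path, invisibly.
#' @export
writeHills <- function(state, path, cv_names = NULL, gamma = 20) {
  d <- state@d
  if (is.null(cv_names)) cv_names <- paste0("cv", seq_len(d))
  hdr <- paste("#! FIELDS time", paste(cv_names, collapse = " "),
               paste(paste0("sigma_", cv_names), collapse = " "),
               "height biasf")
  h <- state@hills
  rows <- vapply(seq_len(nrow(h)), function(k)
    paste(sprintf("%.10g", c(h[k, ], gamma)), collapse = " "), "")
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read hills from the HILLS dialect
#'
#' @param path file with a \code{#! FIELDS} header ending in
#'   \code{height biasf}.
#' @return list with \code{state} (a [BiasState-class]) and
#'   \code{gamma} (from the biasf column).
#' @export
readHills <- function(path) {
  first <- readLines(path, n = 1)
  if (!grepl("^#!\\s*FIELDS", first))
    stop("parse error: ", path, " has no '#! FIELDS' header",
         call. = FALSE)
  fields <- strsplit(sub("^#!\\s*FIELDS\\s+", "", first), "\\s+")[[1]]
  if (tail(fields, 1) != "biasf" || fields[length(fields) - 1] != "height")
    stop("parse error: HILLS header must end in 'height biasf'",
         call. = FALSE)
  d <- (length(fields) - 3) / 2
  if (d != round(d))
    stop("parse error: HILLS header has unbalanced center/sigma columns",
         call. = FALSE)
  df <- read.table(path, comment.char = "#", col.names = fields)
  m <- as.matrix(df[, -ncol(df), drop = FALSE])
  dimnames(m) <- NULL
  list(state = new("BiasState", d = as.integer(d), hills = m),
       gamma = if (nrow(df)) df$biasf[1] else NA_real_)
}

#' Late-window time-averaged bias on a grid
#'
#' The instantaneous well-tempered bias carries a travelling ripple of
#' the order of the late hill height; the converged estimator of
#' \eqn{-(1 - 1/\gamma) F(s)} (up to a constant) is the bias averaged
#' over a late time window.  Averages \eqn{V(s, t)} over the hill
#' times in the final \code{fraction} of the deposition record.
#'
#' @param state a [BiasState-class].
#' @param nodes list of grid-node vectors per CV (or a single vector
#'   for 1 CV).
#' @param fraction trailing fraction of hills averaged over (default
#'   0.25).
#' @return numeric array of averaged bias values on the grid.
#' @export
biasGridAverage <- function(state, nodes, fraction = 0.25) {
  if (!is.list(nodes)) nodes <- list(nodes)
  stopifnot(length(nodes) == state@d, fraction > 0, fraction <= 1)
  h <- state@hills
  d <- state@d
  n <- nrow(h)
  if (!n) stop("biasGridAverage: no hills", call. = FALSE)
  k0 <- floor((1 - fraction) * n)
  V <- array(0, lengths(nodes))
  Vsum <- array(0, lengths(nodes))
  cnt <- 0
  for (k in seq_len(n)) {
    V <- V + .hill_on_grid(nodes, h[k, 2:(1 + d)],
                           h[k, (2 + d):(1 + 2 * d)], h[k, 2 * d + 2],
                           trunc = Inf)
    if (k > k0) { Vsum <- Vsum + V; cnt <- cnt + 1 }
  }
  Vsum / cnt
}
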