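## Reweighting of well-tempered metadynamics samples: the
## time-dependent bias offset c(t), per-frame unbiasing weights,
## free-energy surfaces on unbiased CVs, per-basin free energies with
## block-averaged uncertainties, and a bias-based convergence check.

.grid_expand <- function(mids) {
  if (length(mids) == 1) matrix(mids[[1]], ncol = 1)
  else as.matrix(expand.grid(mids[[1]], mids[[2]]))
}

.logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

#' Time-dependent bias offset c(t)
#'
#' Evaluates, at every hill-deposition time,
#' \deqn{c(t) = \frac{1}{\beta}\ln
#'   \frac{\sum_s e^{\beta \gamma V(s,t)/(\gamma-1)}}
#'        {\sum_s e^{\beta V(s,t)/(\gamma-1)}}}
#' over a grid covering the sampled region of the biased CVs.  This is
#' the standard offset estimator that turns the evolving
#' well-tempered bias into unbiasing weights needing only the hill
#' record.
#'
#' @param state a [BiasState-class] (the hill record).
#' @param mids list of grid-point vectors per biased CV.
#' @param p a [WTMetaDParams-class] (gamma and kT are used).
#' @return data.frame with \code{time}, \code{ct} (kJ/mol).
#' @export
computeCt <- function(state, mids, p) {
  if (!length(mids) || !all(lengths(mids) > 0))
    stop("computeCt: empty grid", call. = FALSE)
  stopifnot(length(mids) == state@d)
  pts <- .grid_expand(mids)
  h <- state@hills
  d <- state@d
  beta <- 1 / p@kT
  g <- p@gamma
  V <- numeric(nrow(pts))
  ct <- numeric(nrow(h))
  for (k in seq_len(nrow(h))) {
    cen <- h[k, 2:(1 + d)]
    sig <- h[k, (2 + d):(1 + 2 * d)]
    z <- sweep(pts, 2, cen)
    V <- V + h[k, 2 * d + 2] *
      exp(-rowSums(sweep(z^2, 2, 2 * sig^2, "/")))
    num <- .logsumexp(beta * g / (g - 1) * V)
    den <- .logsumexp(beta / (g - 1) * V)
    ct[k] <- (num - den) / beta
  }
  data.frame(time = h[, 1], ct = ct)
}

#' Unbiasing frame weights
#'
#' \eqn{w_i \propto \exp[(V(s_i, t_i) - c(t_i)) / kT]}, with c(t)
#' interpolated piecewise-constant (left-continuous) between hill
#' times, normalised to sum 1.  Adding any constant to both V and c
#' leaves the weights unchanged.
#'
#' @param colvar data.frame with \code{time} and \code{bias} columns
#'   (instantaneous bias at the frame's CVs, kJ/mol).
#' @param ct data.frame from [computeCt()] (or NULL for zero offset).
#' @param kT thermal energy, kJ/mol.
#' @return numeric weights summing to 1.
#' @export
frameWeights <- function(colvar, ct = NULL, kT = 2.494) {
  if (!"bias" %in% names(colvar))
    stop("frameWeights: colvar has no 'bias' column", call. = FALSE)
  V <- colvar$bias
  cvals <- if (is.null(ct) || nrow(ct) == 0) rep(0, nrow(colvar))
  else if (nrow(ct) == 1) rep(ct$ct, nrow(colvar))
  else approx(ct$time, ct$ct, xout = colvar$time, method = "constant",
              f = 0, rule = 2)$y
  lw <- (V - cvals) / kT
  w <- exp(lw - max(lw))
  w / sum(w)
}

#' Free-energy surface from weighted samples
#'
#' Bins the unbiased CV values, sums weights per bin, and sets
#' \eqn{F = -kT \ln W}, re-referenced so the minimum over visited bins
#' is zero.  With uniform weights this is exactly the histogram
#' estimator.
#'
#' @param values n x d matrix (or vector) of unbiased CV values.
#' @param weights frame weights (any positive scale).
#' @param breaks list of bin-edge vectors per CV.
#' @param kT thermal energy, kJ/mol.
#' @param cv_names names for the grid axes.
#' @return a [FESGrid-class].
#' @export
fesFromWeights <- function(values, weights, breaks, kT = 2.494,
                           cv_names = NULL) {
  if (!is.matrix(values)) values <- matrix(values, ncol = 1)
  d <- ncol(values)
  stopifnot(length(breaks) == d, all(is.finite(values)))
  if (is.null(cv_names)) cv_names <- paste0("cv", seq_len(d))
  nb <- vapply(breaks, length, 0L) - 1L
  idx <- lapply(seq_len(d), function(i) {
    bi <- findInterval(values[, i], breaks[[i]], rightmost.closed = TRUE)
    bi[bi < 1 | bi > nb[i]] <- NA_integer_
    bi
  })
  W <- array(0, nb)
  flat <- idx[[1]]
  if (d == 2) flat <- idx[[1]] + nb[1] * (idx[[2]] - 1)
  ok <- !is.na(flat)
  tw <- tapply(weights[ok], flat[ok], sum)
  W[as.integer(names(tw))] <- tw
  visited <- array(W > 0, nb)
  F <- array(NA_real_, nb)
  F[visited] <- -kT * log(W[visited])
  F[visited] <- F[visited] - min(F[visited])
  mids <- lapply(breaks, function(b) (head(b, -1) + tail(b, -1)) / 2)
  new("FESGrid", cvNames = cv_names, mids = mids, F = F,
      visited = visited, kT = kT)
}

#' Assign samples to rectangular basins
#'
#' @param values n x d matrix of CV values.
#' @param basins named list; each element a list with \code{lo} and
#'   \code{hi} vectors (inclusive rectangle).  Basins must be pairwise
#'   disjoint.
#' @return character vector of basin names (NA outside all basins).
#' @export
assignBasins <- function(values, basins) {
  if (!is.matrix(values)) values <- matrix(values, ncol = 1)
  nb <- names(basins)
  ## disjointness: rectangles must not overlap pairwise
  if (length(basins) > 1) {
    for (i in seq_along(basins)[-1]) for (j in seq_len(i - 1)) {
      a <- basins[[i]]; b <- basins[[j]]
      if (all(a$lo < b$hi & b$lo < a$hi))
        stop("assignBasins: basins '", nb[i], "' and '", nb[j],
             "' overlap", call. = FALSE)
    }
  }
  out <- rep(NA_character_, nrow(values))
  for (nm in nb) {
    b <- basins[[nm]]
    inb <- rep(TRUE, nrow(values))
    for (i in seq_along(b$lo))
      inb <- inb & values[, i] >= b$lo[i] & values[, i] <= b$hi[i]
    out[inb] <- nm
  }
  out
}

#' Per-basin free energies with block-averaged uncertainties
#'
#' \eqn{F_b = -kT \ln \sum_{i \in b} w_i}, referenced to the deepest
#' basin.  The standard deviation is that of per-block estimates over
#' contiguous, equal-frame-count time blocks (each block renormalised
#' and referenced to the overall deepest basin).  Basins never sampled
#' are excluded with a warning; a basin must appear in at least two
#' blocks to get an uncertainty.
#'
#' @param labels per-frame basin labels (NA = outside all basins).
#' @param weights normalised frame weights.
#' @param n_blocks number of contiguous blocks (default 5).
#' @param kT thermal energy, kJ/mol.
#' @return data.frame with \code{basin}, \code{free_energy},
#'   \code{sd}, \code{n_blocks}, \code{population}.
#' @export
basinFreeEnergy <- function(labels, weights, n_blocks = 5, kT = 2.494) {
  stopifnot(n_blocks >= 2, length(labels) == length(weights))
  present <- sort(unique(labels[!is.na(labels)]))
  if (!length(present))
    stop("basinFreeEnergy: no frames fall in any basin", call. = FALSE)
  Wb <- vapply(present, function(b)
    sum(weights[!is.na(labels) & labels == b]), 0.0)
  names(Wb) <- present
  ref <- present[which.max(Wb)]
  Fb <- -kT * log(Wb / Wb[ref])
  n <- length(labels)
  block <- pmin(ceiling(seq_len(n) / (n / n_blocks)), n_blocks)
  Fblocks <- matrix(NA_real_, n_blocks, length(present),
                    dimnames = list(NULL, present))
  for (j in seq_len(n_blocks)) {
    sel <- block == j
    wj <- vapply(present, function(b)
      sum(weights[sel & !is.na(labels) & labels == b]), 0.0)
    if (wj[ref] > 0)
      Fblocks[j, wj > 0] <- -kT * log(wj[wj > 0] / wj[ref])
  }
  sds <- vapply(present, function(b) {
    v <- Fblocks[, b]
    v <- v[is.finite(v)]
    if (length(v) >= 2) sd(v) else NA_real_
  }, 0.0)
  nbl <- vapply(present, function(b)
    sum(is.finite(Fblocks[, b])), 0L)
  data.frame(basin = present, free_energy = as.numeric(Fb),
             sd = as.numeric(sds), n_blocks = as.integer(nbl),
             population = as.numeric(Wb / sum(Wb)))
}

#' Convergence of the well-tempered bias
#'
#' At each checkpoint time the free-energy estimate
#' \eqn{F \approx -\gamma/(\gamma - 1) V(s, t)} is formed from the
#' hills deposited so far; successive estimates are aligned by
#' subtracting their means over the commonly visited region and the
#' maximum absolute difference is reported.  A converging run shows a
#' decreasing series.
#'
#' @param state a [BiasState-class].
#' @param checkpoints increasing vector of at least two times, ps.
#' @param mids list of grid-point vectors per biased CV.
#' @param p a [WTMetaDParams-class].
#' @param visit_threshold bias level (kJ/mol) above which a grid point
#'   counts as visited.
#' @return data.frame with \code{time} (checkpoint) and
#'   \code{max_abs_dF} versus the previous checkpoint.
#' @export
convergenceCheck <- function(state, checkpoints, mids, p,
                             visit_threshold = 0.5) {
  if (length(checkpoints) < 2)
    stop("convergenceCheck: need at least two checkpoints",
         call. = FALSE)
  stopifnot(!is.unsorted(checkpoints, strictly = TRUE))
  pts <- .grid_expand(mids)
  h <- state@hills
  d <- state@d
  fac <- -p@gamma / (p@gamma - 1)
  V <- numeric(nrow(pts))
  est <- list()
  ki <- 1
  for (ck in seq_along(checkpoints)) {
    while (ki <= nrow(h) && h[ki, 1] <= checkpoints[ck]) {
      cen <- h[ki, 2:(1 + d)]
      sig <- h[ki, (2 + d):(1 + 2 * d)]
      z <- sweep(pts, 2, cen)
      V <- V + h[ki, 2 * d + 2] *
        exp(-rowSums(sweep(z^2, 2, 2 * sig^2, "/")))
      ki <- ki + 1
    }
    est[[ck]] <- list(F = fac * V, visited = V > visit_threshold)
  }
  out <- data.frame(time = checkpoints[-1],
                    max_abs_dF = NA_real_)
  for (ck in 2:length(checkpoints)) {
    common <- est[[ck - 1]]$visited & est[[ck]]$visited
    if (!any(common)) next
    a <- est[[ck - 1]]$F[common]; b <- est[[ck]]$F[common]
    out$max_abs_dF[ck - 1] <- max(abs((b - mean(b)) - (a - mean(a))))
  }
  out
}
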