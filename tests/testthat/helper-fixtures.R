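# Shared fixtures built in code.

simple_structure <- function(xyz, names = NULL, resname = "DG",
                             resid = NULL, element = NULL) {
  xyz <- matrix(xyz, ncol = 3)
  n <- nrow(xyz)
  if (is.null(names)) names <- paste0("C", seq_len(n))
  if (is.null(resid)) resid <- rep(1L, n)
  if (is.null(element)) element <- substr(names, 1, 1)
  G4Structure(data.frame(serial = seq_len(n), name = names,
                         element = element, resname = resname,
                         resid = as.integer(resid), chain = "A",
                         x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                         stringsAsFactors = FALSE))
}

static_trajectory <- function(structure, n_frames = 5, dt = 1) {
  m <- as.matrix(atoms(structure)[, c("x", "y", "z")])
  arr <- array(rep(m, n_frames), c(nrow(m), 3, n_frames))
  G4Trajectory(structure, arr, (seq_len(n_frames) - 1) * dt)
}

random_rotation <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  a <- q[1]; b <- q[2]; c <- q[3]; d <- q[4]
  matrix(c(a^2 + b^2 - c^2 - d^2, 2 * (b * c - a * d), 2 * (b * d + a * c),
           2 * (b * c + a * d), a^2 - b^2 + c^2 - d^2, 2 * (c * d - a * b),
           2 * (b * d - a * c), 2 * (c * d + a * b),
           a^2 - b^2 - c^2 + d^2), 3, 3, byrow = TRUE)
}

# brute-force rigid-fit RMSD: grid over Euler angles + local refinement,
# independent of the svd-based implementation
brute_force_rmsd <- function(P, Q) {
  rot <- function(ang) {
    cz <- cos(ang[1]); sz <- sin(ang[1])
    cy <- cos(ang[2]); sy <- sin(ang[2])
    cx <- cos(ang[3]); sx <- sin(ang[3])
    Rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, 3, byrow = TRUE)
    Ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, 3, byrow = TRUE)
    Rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, 3, byrow = TRUE)
    Rz %*% Ry %*% Rx
  }
  Pc <- sweep(P, 2, colMeans(P))
  Qc <- sweep(Q, 2, colMeans(Q))
  f <- function(ang) sqrt(mean(rowSums((Pc %*% t(rot(ang)) - Qc)^2)))
  best <- NULL
  gr <- seq(0, 2 * pi - 0.35, by = 0.35)
  for (a1 in gr) for (a2 in seq(0, pi, by = 0.35)) for (a3 in gr) {
    v <- f(c(a1, a2, a3))
    if (is.null(best) || v < best$value)
      best <- list(par = c(a1, a2, a3), value = v)
  }
  o <- optim(best$par, f, control = list(reltol = 1e-14, maxit = 5000))
  o$value
}

# well-to-well transition count with hysteresis at +-0.5
well_crossings <- function(s, lo = -0.5, hi = 0.5) {
  st <- 0L; n <- 0L
  for (x in s) {
    if (x < lo) { if (st == 1L) n <- n + 1L; st <- -1L }
    else if (x > hi) { if (st == -1L) n <- n + 1L; st <- 1L }
  }
  n
}
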