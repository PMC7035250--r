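test_that("the bias offset c(t) vanishes for zero bias and equals a constant bias", {
  p <- wtMetaDParams(sigma = 1)
  mids <- list(seq(-2, 2, length.out = 101))
  ## essentially zero bias
  st <- new("BiasState", d = 1L,
            hills = matrix(c(1, 0, 1, 1e-12), 1, 4))
  expect_equal(computeCt(st, mids, p)$ct, 0, tolerance = 1e-10)
  ## a near-constant bias of height h over the grid gives c = h
  st2 <- new("BiasState", d = 1L,
             hills = matrix(c(1, 0, 1e6, 3.7), 1, 4))
  expect_equal(computeCt(st2, mids, p)$ct, 3.7, tolerance = 1e-4)
  expect_error(computeCt(st2, list(numeric()), p), "empty grid")
})

test_that("c(t) matches an independent high-resolution quadrature of the same functional", {
  pot <- makeModelPotential("double_well_1d")
  p <- wtMetaDParams(sigma = 0.1, kT = 2.494, gamma = 20)
  r <- runLangevinWTMetaD(pot, p, n_steps = 4e5, dt = 0.002, s0 = -1,
                          grid = list(c(-2.2, 2.2, 441)), seed = 13)
  mids <- seq(-1.9, 1.9, length.out = 191)
  ct <- computeCt(r$bias, list(mids), p)
  ## oracle: direct hill summation on a 10x finer grid, trapezoid sums
  fine <- seq(-1.9, 1.9, length.out = 1901)
  V <- biasAt(r$bias, matrix(fine, ncol = 1))$value
  beta <- 1 / p@kT; g <- p@gamma
  lse <- function(x) { m <- max(x); m + log(sum(exp(x - m))) }
  oracle <- (lse(beta * g / (g - 1) * V) - lse(beta / (g - 1) * V)) / beta
  expect_equal(tail(ct$ct, 1), oracle, tolerance = 0.05)
})

test_that("frame weights obey the closed forms and gauge invariance", {
  kT <- 2.494
  cv <- data.frame(time = c(1, 2), bias = c(0, 0))
  expect_equal(frameWeights(cv, NULL, kT), c(0.5, 0.5))
  ## bias difference of kT ln 2 with equal offset -> exact weight ratio 2
  cv2 <- data.frame(time = c(1, 2), bias = c(kT * log(2), 0))
  w <- frameWeights(cv2, NULL, kT)
  expect_equal(w[1] / w[2], 2, tolerance = 1e-12)
  expect_equal(frameWeights(data.frame(time = 1, bias = 5), NULL, kT), 1)
  expect_error(frameWeights(data.frame(time = 1, v = 2)), "bias")
  ## adding a constant to both V and c leaves weights unchanged
  ct <- data.frame(time = c(0.5, 1.5), ct = c(1, 2))
  w1 <- frameWeights(cv2, ct, kT)
  ct2 <- ct; ct2$ct <- ct2$ct + 7.3
  cv3 <- cv2; cv3$bias <- cv3$bias + 7.3
  expect_equal(frameWeights(cv3, ct2, kT), w1, tolerance = 1e-10)
  expect_true(all(w1 >= 0))
  expect_equal(sum(w1), 1)
})

test_that("weighted FES reproduces closed-form bin differences", {
  kT <- 2.494
  vals <- c(0.25, 0.25, 0.75, 0.75)
  fes <- fesFromWeights(vals, rep(0.25, 4), list(c(0, 0.5, 1)), kT)
  expect_equal(fes@F, array(c(0, 0), 2))
  ## weight ratio e -> exactly kT
  fes2 <- fesFromWeights(c(0.25, 0.75), c(exp(1), 1) / (exp(1) + 1),
                         list(c(0, 0.5, 1)), kT)
  expect_equal(fes2@F[2] - fes2@F[1], kT)
  expect_equal(min(fes2@F[fes2@visited]), 0)
  ## unvisited bins are NA and flagged
  fes3 <- fesFromWeights(c(0.1, 0.9), c(0.5, 0.5),
                         list(seq(0, 1, by = 0.25)), kT)
  expect_true(is.na(fes3@F[2]))
  expect_false(fes3@visited[2])
})

test_that("with uniform weights the FES equals the plain histogram estimator", {
  set.seed(21)
  x <- rnorm(5000)
  breaks <- seq(-4, 4, length.out = 41)
  kT <- 2.494
  fes <- fesFromWeights(x, rep(1 / 5000, 5000), list(breaks), kT)
  counts <- hist(x, breaks = breaks, plot = FALSE)$counts
  Fhist <- -kT * log(counts / 5000)
  Fhist <- Fhist - min(Fhist[counts > 0])
  expect_equal(as.numeric(fes@F[counts > 0]), Fhist[counts > 0],
               tolerance = 1e-12)
})

test_that("basin free energies and block uncertainties behave analytically", {
  kT <- 2.494
  ## two basins with equal total weight -> dF = 0
  lab <- rep(c("A", "B"), each = 50)
  w <- rep(1 / 100, 100)
  bfe <- basinFreeEnergy(lab, w, n_blocks = 2, kT = kT)
  expect_equal(bfe$free_energy, c(0, 0))
  ## 4 identical blocks -> sd exactly 0
  lab4 <- rep(c("A", "A", "B"), 40)
  w4 <- rep(1 / 120, 120)
  bfe4 <- basinFreeEnergy(lab4, w4, n_blocks = 4, kT = kT)
  expect_equal(bfe4$sd, c(0, 0), tolerance = 1e-12)
  expect_equal(bfe4$free_energy[bfe4$basin == "B"], kT * log(2),
               tolerance = 1e-10)
  expect_equal(bfe4$n_blocks, c(4L, 4L))
  ## weight ratio e between basins -> dF = kT exactly
  labr <- c(rep("A", 10), rep("B", 10))
  wr <- c(rep(exp(1), 10), rep(1, 10))
  wr <- wr / sum(wr)
  bfer <- basinFreeEnergy(labr, wr, n_blocks = 2, kT = kT)
  expect_equal(bfer$free_energy[bfer$basin == "B"], kT)
  expect_error(basinFreeEnergy(rep(NA_character_, 10), rep(0.1, 10)),
               "no frames")
})

test_that("rectangular basin assignment is exclusive and validated", {
  basins <- list(A = list(lo = c(-3, -1), hi = c(-1, 1)),
                 B = list(lo = c(1, -1), hi = c(3, 1)))
  v <- rbind(c(-2, 0), c(2, 0), c(0, 5))
  expect_equal(assignBasins(v, basins), c("A", "B", NA))
  bad <- list(A = list(lo = c(-1, -1), hi = c(1, 1)),
              B = list(lo = c(0, 0), hi = c(2, 2)))
  expect_error(assignBasins(v, bad), "overlap")
})

test_that("convergence check reports shrinking differences on a converging run", {
  pot <- makeModelPotential("double_well_1d")
  p <- wtMetaDParams(sigma = 0.1)
  r <- runLangevinWTMetaD(pot, p, n_steps = 1e6, dt = 0.002, s0 = -1,
                          grid = list(c(-2.2, 2.2, 441)), seed = 17)
  mids <- list(seq(-1.8, 1.8, length.out = 181))
  cc <- convergenceCheck(r$bias, c(500, 1000, 1500, 2000), mids, p)
  expect_equal(nrow(cc), 3)
  expect_lt(tail(cc$max_abs_dF, 1), cc$max_abs_dF[1])
  ## identical bias at both checkpoints -> 0 (both after the last hill)
  tend <- max(hills(r$bias)[, 1])
  cc0 <- convergenceCheck(r$bias, c(tend + 1, tend + 2), mids, p)
  expect_equal(cc0$max_abs_dF, 0)
  expect_error(convergenceCheck(r$bias, 1000, mids, p), "two checkpoints")
})
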