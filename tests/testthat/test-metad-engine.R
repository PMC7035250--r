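test_that("well-tempered hill height follows its closed form", {
  p <- wtMetaDParams()
  expect_equal(hillHeight(0, p), 2.48)
  expect_equal(hillHeight((p@gamma - 1) * p@kT, p), 2.48 / exp(1))
  ## enormous bias factor recovers standard (constant-height) MetaD
  pinf <- wtMetaDParams(gamma = 1e9)
  expect_equal(hillHeight(1000, pinf), 2.48, tolerance = 1e-6)
})

test_that("fixed-point deposition follows the analytic height recursion", {
  p <- wtMetaDParams(sigma = 0.2)
  st <- biasState(1)
  Vsum <- 0
  for (k in 1:25) {
    st <- depositHill(st, 0.3, k, p)
    h_expected <- p@w0 * exp(-Vsum / ((p@gamma - 1) * p@kT))
    expect_equal(hills(st)[k, 4], h_expected, tolerance = 1e-10)
    Vsum <- Vsum + hills(st)[k, 4]
  }
  ## heights strictly positive and non-increasing at a fixed point
  h <- hills(st)[, 4]
  expect_true(all(h > 0))
  expect_true(all(diff(h) <= 0))
  expect_error(depositHill(st, 0.3, 10, p), "not after")
  ## a hill dropped far from all others starts at full height
  st <- depositHill(st, 0.3 + 10 * 0.2, 26, p)
  expect_equal(tail(hills(st)[, 4], 1), 2.48, tolerance = 1e-9)
})

test_that("biasAt sums Gaussians with analytic gradients", {
  p <- wtMetaDParams(sigma = 0.5)
  st <- biasState(1)
  expect_equal(biasAt(st, 0)$value, 0)
  expect_equal(biasAt(st, 0)$gradient[1, 1], 0)
  st <- depositHill(st, 1.0, 1, p)
  expect_equal(biasAt(st, 1.0)$value, 2.48)
  expect_equal(biasAt(st, 1.0)$gradient[1, 1], 0, tolerance = 1e-12)
  ## superposed identical hills double the height (gamma damping aside)
  v1 <- biasAt(st, 1.0)$value
  st2 <- depositHill(st, 1.0, 2, p)
  v2 <- biasAt(st2, 1.0)$value
  expect_equal(v2, v1 + hills(st2)[2, 4])
  ## gradient matches finite differences off-center
  g <- biasAt(st, 1.3)$gradient[1, 1]
  fd <- (biasAt(st, 1.3 + 1e-6)$value - biasAt(st, 1.3 - 1e-6)$value) / 2e-6
  expect_equal(g, fd, tolerance = 1e-5)
})

test_that("grid cache agrees with direct summation at its nodes", {
  p <- wtMetaDParams(sigma = 0.3)
  st <- biasState(1)
  set.seed(4)
  for (k in 1:40) st <- depositHill(st, rnorm(1), k, p)
  nodes <- list(seq(-3, 3, length.out = 301))
  st <- attachBiasGrid(st, nodes)
  direct <- biasAt(st, matrix(nodes[[1]], ncol = 1))$value
  expect_lt(max(abs(st@gridValues - direct)), 1e-6)
  ## the engine's own cache satisfies the same bound
  pot <- makeModelPotential("harmonic")
  r <- runLangevinWTMetaD(pot, wtMetaDParams(sigma = 0.3),
                          n_steps = 2e4, dt = 0.002, s0 = 0,
                          grid = list(c(-4, 4, 201)), seed = 2)
  direct2 <- biasAt(r$bias, matrix(r$bias@gridNodes[[1]], ncol = 1))$value
  expect_lt(max(abs(r$bias@gridValues - direct2)), 1e-6)
})

test_that("lower wall is zero on the allowed side and polynomial below", {
  w <- wallRestraint(1, threshold = 5, kappa = 500, exp = 2)
  expect_equal(wallEnergy(5, w)$value, 0)
  expect_equal(wallEnergy(15, w)$value, 0)
  expect_equal(wallEnergy(4, w)$value, 500)
  expect_equal(wallEnergy(4, w)$gradient, -1000)
  ## the engine respects walls: with a strong lower wall at 0.5 the
  ## harmonic walker stays on the positive side
  pot <- makeModelPotential("harmonic")
  r <- runLangevinWTMetaD(pot, wtMetaDParams(w0 = 0, sigma = 0.1),
                          walls = list(wallRestraint(1, 0.5)),
                          n_steps = 5e4, dt = 0.002, s0 = 1,
                          grid = list(c(-4, 4, 201)), seed = 3)
  expect_gt(quantile(r$colvar$cv1, 0.01), 0.2)
})

test_that("runs are bit-reproducible for a fixed seed", {
  pot <- makeModelPotential("double_well_1d")
  p <- wtMetaDParams(sigma = 0.1)
  r1 <- runLangevinWTMetaD(pot, p, n_steps = 5e4, dt = 0.002, s0 = -1,
                           grid = list(c(-2.2, 2.2, 221)), seed = 11)
  r2 <- runLangevinWTMetaD(pot, p, n_steps = 5e4, dt = 0.002, s0 = -1,
                           grid = list(c(-2.2, 2.2, 221)), seed = 11)
  expect_identical(r1$colvar, r2$colvar)
  expect_identical(hills(r1$bias), hills(r2$bias))
  r3 <- runLangevinWTMetaD(pot, p, n_steps = 5e4, dt = 0.002, s0 = -1,
                           grid = list(c(-2.2, 2.2, 221)), seed = 12)
  expect_false(identical(r1$colvar, r3$colvar))
})

test_that("unbiased harmonic sampling satisfies equipartition", {
  pot <- makeModelPotential("harmonic", k = 10)
  p <- wtMetaDParams(w0 = 0, sigma = 0.1, kT = 2.494)
  r <- runLangevinWTMetaD(pot, p, n_steps = 1e6, dt = 0.002,
                          friction = 1, s0 = 0,
                          grid = list(c(-3, 3, 601)), seed = 7)
  v <- var(r$colvar$cv1[-(1:5000)])
  expect_equal(v, 2.494 / 10, tolerance = 0.05)
})

test_that("total bias grows monotonically in time at any fixed point", {
  pot <- makeModelPotential("double_well_1d")
  p <- wtMetaDParams(sigma = 0.1)
  r <- runLangevinWTMetaD(pot, p, n_steps = 2e5, dt = 0.002, s0 = -1,
                          grid = list(c(-2.2, 2.2, 221)), seed = 5)
  h <- hills(r$bias)
  probe <- c(-1, 0, 1)
  for (s in probe) {
    partial <- vapply(seq(100, nrow(h), by = 200), function(k) {
      st <- new("BiasState", d = 1L, hills = h[1:k, , drop = FALSE])
      biasAt(st, s)$value
    }, 0.0)
    expect_true(all(diff(partial) >= -1e-9))
  }
})

test_that("hill records round-trip through the HILLS dialect", {
  pot <- makeModelPotential("double_well_1d")
  r <- runLangevinWTMetaD(pot, wtMetaDParams(sigma = 0.1),
                          n_steps = 2e4, dt = 0.002, s0 = -1,
                          grid = list(c(-2.2, 2.2, 221)), seed = 6)
  tf <- tempfile()
  writeHills(r$bias, tf, gamma = 20)
  expect_match(readLines(tf, n = 1),
               "^#! FIELDS time cv1 sigma_cv1 height biasf$")
  back <- readHills(tf)
  expect_equal(back$gamma, 20)
  expect_equal(hills(back$state), hills(r$bias), tolerance = 1e-9)
  ## hill count arithmetic: one hill per pace interval
  expect_equal(nHills(r$bias), floor(2e4 * 0.002 / 1))
  expect_equal(hills(r$bias)[1, 4], 2.48, tolerance = 1e-9)
})
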