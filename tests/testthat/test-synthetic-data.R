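test_that("ideal native geometry satisfies the G4 construction constraints", {
  s <- buildIdealG4("native")
  a <- atoms(s)
  ## Hoogsteen donor-acceptor distances within tetrads: 2.8 - 3.1 A
  pr <- hoogsteenPairs(applySlip(code = "native"), s)
  d <- sqrt(rowSums((coords(s)[pr[, 1], ] - coords(s)[pr[, 2], ])^2))
  expect_true(all(d > 2.8 & d < 3.1))
  ## base heavy atoms of each guanine are coplanar within 0.1 A
  ring_atoms <- c("N9", "C8", "N7", "C5", "C6", "O6", "N1", "C2", "N2",
                  "N3", "C4")
  for (r in c(2, 9, 16, 22)) {
    m <- coords(s)[a$resid == r & a$name %in% ring_atoms, ]
    sv <- svd(sweep(m, 2, colMeans(m)))
    expect_lt(sv$d[3] / sqrt(nrow(m)), 0.1)
  }
  ## consecutive in-column base centroids one rise apart along z
  cent <- function(r) colMeans(coords(s)[a$resid == r & a$name %in% ring_atoms, ])
  for (col in defaultStrandLayout()) {
    z <- vapply(col, function(r) cent(r)[3], 0.0)
    expect_equal(diff(z), c(-3.4, -3.4), tolerance = 1e-6)
  }
  ## two channel cations between the three planes
  expect_equal(sum(a$resname == "K"), 2)
})

test_that("slipped-out guanines continue the helix one rise beyond the core", {
  s <- buildIdealG4("4d", cations = FALSE, triad_form = "none")
  a <- atoms(s)
  z22 <- mean(coords(s)[a$resid == 22, 3])
  z21 <- mean(coords(s)[a$resid == 21, 3])
  expect_equal(z21 - z22, 3.4, tolerance = 0.05)
  expect_error(buildIdealG4("9z"), "unknown slip code")
})

test_that("every enumerated code yields a separable ideal structure", {
  nat <- buildIdealG4("native")
  specs <- topologyCVSpecs(nat)
  for (code in names(enumerateTopologies(max_simultaneous_moves = 2))) {
    s <- buildIdealG4(code)
    got <- classifyFrame(s, specs)
    expect_equal(got$label, code, info = code)
  }
})

test_that("transition trajectories are reproducible and endpoint-faithful", {
  t1 <- transitionTrajectory(list("native", "4d"), frames_per_segment = 10,
                             noise_sd = 0, seed = 1)
  t2 <- transitionTrajectory(list("native", "4d"), frames_per_segment = 10,
                             noise_sd = 0, seed = 999)
  expect_identical(coords(t1), coords(t2))  # noiseless: seed-independent
  n1 <- transitionTrajectory(list("native", "4d"), frames_per_segment = 10,
                             noise_sd = 0.3, seed = 5)
  n2 <- transitionTrajectory(list("native", "4d"), frames_per_segment = 10,
                             noise_sd = 0.3, seed = 5)
  expect_identical(coords(n1), coords(n2))
  specs <- topologyCVSpecs(buildIdealG4("native", cations = FALSE))
  expect_equal(classifyFrame(coords(t1, 1), specs)$label, "A-like")
  expect_equal(classifyFrame(coords(t1, 10), specs)$label, "4d")
  ## multi-leg paths must be move-adjacent
  expect_error(transitionTrajectory(list("native", "24d")),
               "not adjacent")
  t3 <- transitionTrajectory(list("native", "4d", "24d"),
                             frames_per_segment = 5, noise_sd = 0,
                             seed = 1)
  expect_equal(nFrames(t3), 9)
})

test_that("generated fixtures are byte-identical across reruns", {
  f1 <- tempfile(fileext = ".pdb")
  f2 <- tempfile(fileext = ".pdb")
  writeTrajectory(transitionTrajectory(list("native", "2d"),
                                       frames_per_segment = 4,
                                       noise_sd = 0.3, seed = 7), f1)
  writeTrajectory(transitionTrajectory(list("native", "2d"),
                                       frames_per_segment = 4,
                                       noise_sd = 0.3, seed = 7), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("model potentials expose correct analytics", {
  h <- makeModelPotential("harmonic", k = 10)
  sgrid <- seq(-2, 2, by = 0.1)
  expect_equal(h@U(matrix(sgrid, ncol = 1)), 5 * sgrid^2)
  dw <- makeModelPotential("double_well_1d", barrier = 15, asymmetry = 3)
  ## asymmetry tilts the right-hand well up by about 3 kJ/mol
  expect_equal(dw@U(matrix(1, 1, 1)) - dw@U(matrix(-1, 1, 1)), 3,
               tolerance = 1e-12)
  expect_equal(dw@U(matrix(0, 1, 1)) - dw@U(matrix(-1, 1, 1)),
               15 + 1.5, tolerance = 1e-12)
  ## the quadrature well gap agrees with an independent integrate() oracle
  gap <- wellFreeEnergyGap(dw, kT = 2.494)
  oracle <- -2.494 * (log(integrate(function(x) exp(-dw@U(matrix(x, ncol = 1)) / 2.494),
                                    0, 3, rel.tol = 1e-12)$value) -
                      log(integrate(function(x) exp(-dw@U(matrix(x, ncol = 1)) / 2.494),
                                    -3, 0, rel.tol = 1e-12)$value))
  expect_equal(gap, oracle, tolerance = 1e-6)
  tb <- makeModelPotential("three_basin_2d")
  grid <- as.matrix(expand.grid(seq(-3, 3, by = 0.05),
                                seq(-3, 3, by = 0.05)))
  u <- tb@U(grid)
  expect_equal(as.numeric(grid[which.min(u), ]), c(-2, 0),
               tolerance = 0.06)
  ## basin ordering A < B < C by construction
  expect_lt(tb@U(matrix(c(-2, 0), 1)), tb@U(matrix(c(0, 2), 1)))
  expect_lt(tb@U(matrix(c(0, 2), 1)), tb@U(matrix(c(2, 0), 1)))
  expect_error(makeModelPotential("mexican_hat"))
  ## analytic gradients match finite differences
  for (pt in list(matrix(c(0.3, -0.4), 1), matrix(c(-1.5, 0.2), 1))) {
    g <- tb@grad(as.numeric(pt))
    for (i in 1:2) {
      e <- numeric(2); e[i] <- 1e-6
      fd <- (tb@U(pt + e) - tb@U(pt - e)) / 2e-6
      expect_equal(g[i], fd, tolerance = 1e-4)
    }
  }
})
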