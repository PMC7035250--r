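test_that("Kabsch superposition recovers rigid transforms exactly", {
  set.seed(2)
  P <- matrix(rnorm(30), 10, 3)
  expect_equal(superpose(P, P)$rmsd, 0, tolerance = 1e-12)
  for (i in 1:5) {
    R <- random_rotation()
    Q <- P %*% t(R) + matrix(rnorm(3), 10, 3, byrow = TRUE)
    sp <- superpose(P, Q)
    expect_lt(sp$rmsd, 1e-8)
    expect_equal(det(sp$rotation), 1, tolerance = 1e-8)
    ## and the rmsd of either input is invariant under further
    ## proper rigid motion
    R2 <- random_rotation()
    expect_equal(superpose(P %*% t(R2), Q)$rmsd, sp$rmsd,
                 tolerance = 1e-8)
  }
})

test_that("superposition RMSD matches a brute-force rotational search", {
  set.seed(5)
  P <- rbind(c(0, 0, 0), c(2, 0, 0), c(0, 2, 0), c(0, 0, 2))
  Q <- P
  Q[4, ] <- Q[4, ] + c(0.6, -0.5, 0.63)  # ~1 A displacement
  got <- superpose(P, Q)$rmsd
  oracle <- brute_force_rmsd(P, Q)
  expect_equal(got, oracle, tolerance = 1e-6)
  ## cross-check against the field-standard implementation
  ref <- bio3d::rmsd(as.numeric(t(P)), as.numeric(t(Q)), fit = TRUE)
  expect_equal(got, ref, tolerance = 1e-3)
})

test_that("superposition rejects mismatched and degenerate inputs", {
  P <- matrix(rnorm(12), 4, 3)
  expect_error(superpose(P, P[1:3, ]), "atom count")
  line <- cbind(1:5, 1:5, 1:5)
  expect_error(superpose(line, line), "degenerate")
  expect_error(superpose(P[1:2, ], P[1:2, ]), "3 atoms")
})

test_that("rmsdSeries is zero on a static trajectory and tracks injected noise", {
  s <- buildIdealG4("native")
  st <- static_trajectory(s, 4)
  rs <- rmsdSeries(st, s, "name N9,C8,N7,C5,C6,O6,N1,C2,N2,N3,C4")
  expect_equal(rs$rmsd, rep(0, 4), tolerance = 1e-10)
  ## isotropic Gaussian noise of width sigma: mean fitted RMSD ~ sigma*sqrt(3)
  sigma <- 0.2
  set.seed(9)
  n <- nAtoms(s)
  arr <- array(rep(coords(s), 40), c(n, 3, 40)) +
    array(rnorm(n * 3 * 40, sd = sigma), c(n, 3, 40))
  noisy <- G4Trajectory(s, arr, seq_len(40) - 1)
  rs2 <- rmsdSeries(noisy, s, "name N9,C8,N7,C5,C6,O6,N1,C2,N2,N3,C4")
  expect_equal(mean(rs2$rmsd), sigma * sqrt(3), tolerance = 0.1)
  expect_error(rmsdSeries(st, s, "resname XX"), "no atoms")
})

test_that("G-core RMSD increases monotonically in trend along a slippage transition", {
  traj <- transitionTrajectory(list("native", "4d"),
                               frames_per_segment = 40, noise_sd = 0,
                               seed = 1)
  ref <- buildIdealG4("native", cations = FALSE)
  rs <- rmsdSeries(traj, ref, "name N9,C8,N7,C5,C6,O6,N1,C2,N2,N3,C4")
  expect_gt(cor(rs$time_ps, rs$rmsd), 0.99)
  expect_lt(rs$rmsd[1], 1e-6)
  expect_gt(tail(rs$rmsd, 1), 0.5)
})

test_that("rmsf is zero for static input and ranks jittered residues highest", {
  s <- buildIdealG4("native", cations = FALSE)
  st <- static_trajectory(s, 5)
  fl <- rmsf(st, "name N9,C8,N7,C5,C6,O6,N1,C2,N2,N3,C4")
  expect_true(all(fl$rmsf < 1e-10))
  expect_error(rmsf(static_trajectory(s, 1), "name N9"), "2 frames")
  ## jitter residue 9 only
  set.seed(3)
  n <- nAtoms(s)
  arr <- array(rep(coords(s), 30), c(n, 3, 30))
  idx <- which(atoms(s)$resid == 9)
  arr[idx, , ] <- arr[idx, , ] + rnorm(length(idx) * 3 * 30, sd = 0.5)
  tr <- G4Trajectory(s, arr, seq_len(30) - 1)
  fl2 <- rmsf(tr, "name N9,C8,N7,C5,C6,O6,N1,C2,N2,N3,C4")
  expect_equal(fl2$resid[which.max(fl2$rmsf)], 9)
  expect_true(all(fl2$rmsf >= 0))
})

test_that("glycosidic chi reproduces constructed torsions and the syn/anti convention", {
  for (chi in c(60, -120, 180, 89.9, 90.5, -89.5)) {
    s <- buildIdealG4("native", chi1 = chi)
    got <- glycosidicChi(s, 1)
    expect_equal(got$chi, chi, tolerance = 1e-6)
    expect_equal(got$label,
                 if (got$chi > -90 && got$chi <= 90) "syn" else "anti")
  }
  s <- buildIdealG4("native")
  expect_error(glycosidicChi(s, 7), "missing atom")
})

test_that("contact counts match ideal channel geometry", {
  s <- buildIdealG4("native")
  a <- atoms(s)
  o6 <- which(a$name == "O6")
  ## a K+ placed at the centroid of one tetrad's four O6
  top <- which(a$name == "O6" & a$resid %in% c(2, 8, 14, 20))
  cent <- colMeans(coords(s)[top, ])
  probe <- rbind(coords(s), cent)
  expect_equal(contactCount(probe, nrow(probe), top, 3.5), 4)
  ## bipyramidal inter-plane site in the open 4d triad: 3 + 4 contacts
  s4 <- buildIdealG4("4d", triad_form = "open")
  a4 <- atoms(s4)
  o64 <- which(a4$name == "O6")
  ks <- which(a4$resname == "K")
  counts <- vapply(ks, function(k) contactCount(s4, k, o64, 3.5), 0L)
  expect_true(7 %in% counts)
  expect_equal(contactCount(s, integer(), o6, 3.5), 0L)
  ## monotone non-decreasing in the cutoff
  cc <- vapply(c(2, 3, 3.5, 4, 6), function(ct)
    contactCount(s4, ks, o64, ct), 0L)
  expect_true(all(diff(cc) >= 0))
})

test_that("water bridges require both residues within reach", {
  base <- rbind(c(0, 0, 0), c(5.6, 0, 0))
  mkfix <- function(wat_x) {
    xyz <- rbind(base, c(wat_x, 0, 0))
    simple_structure(xyz, names = c("O6", "N7", "O"),
                     resname = c("DG", "DG", "HOH"),
                     resid = c(2L, 14L, 50L))
  }
  expect_equal(waterBridgeCount(mkfix(2.8), 2, 14, 3.5), 1)   # 2.8 from both
  expect_equal(waterBridgeCount(mkfix(10.6), 2, 14, 3.5), 0)  # 5 A past G14
  s <- simple_structure(base, names = c("O6", "N7"),
                        resname = c("DG", "DG"), resid = c(2L, 14L))
  expect_equal(waterBridgeCount(s, 2, 14, 3.5), 0)            # no waters
  ## generator's open-triad fixture carries the two bridging waters
  s4 <- buildIdealG4("4d", triad_form = "open", waters = TRUE)
  expect_equal(waterBridgeCount(s4, 2, 14, 3.5), 2)
})
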