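expected_comp <- function(comp, tetrads, triads = list(), ends = character(),
                          unpaired = integer()) {
  expect_equal(lapply(tetrads(comp), sort), lapply(tetrads, sort))
  expect_equal(lapply(triads(comp), sort), lapply(triads, sort))
  expect_equal(comp@triadEnds, ends)
  expect_equal(sort(unpaired(comp)), sort(as.integer(unpaired)))
}

test_that("applySlip reproduces the published single-slip compositions", {
  expected_comp(applySlip(code = "2d"),
                list(c(3L, 8L, 15L, 21L), c(4L, 9L, 16L, 22L)),
                list(c(2L, 14L, 20L)), "5'", 10L)
  expected_comp(applySlip(code = "3d"),
                list(c(3L, 9L, 14L, 21L), c(4L, 10L, 15L, 22L)),
                list(c(2L, 8L, 20L)), "5'", 16L)
  expected_comp(applySlip(code = "3u"),
                list(c(2L, 8L, 15L, 20L), c(3L, 9L, 16L, 21L)),
                list(c(4L, 10L, 22L)), "3'", 14L)
  expected_comp(applySlip(code = "4d"),
                list(c(3L, 9L, 15L, 20L), c(4L, 10L, 16L, 21L)),
                list(c(2L, 8L, 14L)), "5'", 22L)
})

test_that("double slips leave no triad, only stranded guanine pairs", {
  expected_comp(applySlip(code = "24d"),
                list(c(3L, 8L, 15L, 20L), c(4L, 9L, 16L, 21L)),
                unpaired = c(2L, 14L, 10L, 22L))
  expected_comp(applySlip(code = "34d"),
                list(c(3L, 9L, 14L, 20L), c(4L, 10L, 15L, 21L)),
                unpaired = c(2L, 8L, 16L, 22L))
})

test_that("applySlip conserves the 12 core guanines for every code", {
  all12 <- sort(unlist(defaultStrandLayout()))
  codes <- c("native", "1d", "1u", "2d", "2u", "3d", "3u", "4d", "4u",
             "24d", "34d", "12d", "2d3u")
  for (cd in codes) {
    comp <- applySlip(code = cd)
    expect_equal(sort(c(unlist(tetrads(comp)), unlist(triads(comp)),
                        unpaired(comp))), all12, info = cd)
  }
  nat <- applySlip(code = "native")
  expect_length(tetrads(nat), 3)
  expect_length(triads(nat), 0)
  expect_length(unpaired(nat), 0)
  expect_error(applySlip(code = slipCode("conflict",
    data.frame(column = c(2L, 2L), dir = c("u", "d")))))
})

test_that("enumeration yields 8 single-slip candidates and the reported doubles", {
  singles <- enumerateTopologies(max_simultaneous_moves = 1)
  expect_length(singles, 8)
  expect_true(all(c("2d", "3d", "3u", "4d") %in% names(singles)))
  both <- enumerateTopologies(max_simultaneous_moves = 2)
  expect_true(all(c("24d", "34d") %in% names(both)))
  expect_equal(lapply(tetrads(both[["34d"]]), sort),
               list(c(3L, 9L, 14L, 20L), c(4L, 10L, 15L, 21L)))
  ## a 2-column layout cannot retain any full tetrad
  expect_length(enumerateTopologies(list(c(2L, 3L, 4L), c(8L, 9L, 10L)), 1), 0)
  ## inverse-move consistency: an up-slip is the 5'<->3' mirror image
  ## of the matching down-slip (plane j <-> 4 - j)
  layout <- defaultStrandLayout()
  mirror <- function(r) {
    for (col in layout) {
      j <- match(r, col)
      if (!is.na(j)) return(col[4 - j])
    }
    NA_integer_
  }
  for (col in 1:4) {
    dn <- applySlip(code = paste0(col, "d"))
    up <- applySlip(code = paste0(col, "u"))
    mt <- lapply(rev(tetrads(dn)), function(t)
      sort(vapply(t, mirror, 0L)))
    expect_equal(lapply(tetrads(up), sort), mt)
    expect_equal(sort(vapply(triads(dn)[[1]], mirror, 0L)),
                 sort(triads(up)[[1]]))
    expect_equal(setdiff(c("5'", "3'"), dn@triadEnds), up@triadEnds)
  }
})

test_that("hoogsteenPairs generates two bonds per cyclic tetrad edge", {
  s <- buildIdealG4("native")
  one <- new("TetradComposition", tetrads = list(c(2L, 8L, 14L, 20L)))
  expect_equal(nrow(hoogsteenPairs(one, s)), 8)
  expect_equal(nrow(hoogsteenPairs(applySlip(code = "2d"), s)), 16)
  expect_equal(nrow(hoogsteenPairs(new("TetradComposition"), s)), 0)
  ## one-bond-per-edge convention halves the list
  expect_equal(nrow(hoogsteenPairs(one, s, both_bonds = FALSE)), 4)
  ## triad edges of the open form add 2 edges x 2 bonds
  comp4 <- applySlip(code = "4d")
  expect_equal(nrow(hoogsteenPairs(comp4, s, include_triads = TRUE)),
               16 + 4)
  ## generated pair distances on the matching ideal structure are
  ## within hydrogen-bonding range
  s2 <- buildIdealG4("2d")
  pr <- hoogsteenPairs(applySlip(code = "2d"), s2)
  d <- sqrt(rowSums((coords(s2)[pr[, 1], ] - coords(s2)[pr[, 2], ])^2))
  expect_true(all(d > 2.6 & d < 3.2))
})

test_that("frame classification labels every ideal topology correctly", {
  nat <- buildIdealG4("native")
  specs <- topologyCVSpecs(nat)
  for (code in c("2d", "3d", "3u", "4d", "24d", "34d")) {
    got <- classifyFrame(buildIdealG4(code), specs)
    expect_equal(got$label, code)
  }
  expect_equal(classifyFrame(nat, specs)$label, "A-like")
  expect_equal(classifyFrame(coords(nat) * 20, specs)$label, "unassigned")
  expect_error(classifyFrame(nat, specs[names(specs) != "native"]),
               "native")
})

test_that("triad forms distinguish open, closed and dispersed geometries", {
  comp4 <- applySlip(code = "4d")
  open4 <- buildIdealG4("4d", triad_form = "open")
  expect_equal(classifyTriadForm(open4, triads(comp4)[[1]]), "open")
  ## same canonical geometry with the cation stripped is no longer open
  nocat <- buildIdealG4("4d", triad_form = "none", cations = FALSE)
  expect_equal(classifyTriadForm(nocat, triads(comp4)[[1]]), "closed")
  comp2 <- applySlip(code = "2d")
  closed2 <- buildIdealG4("2d", triad_form = "closed")
  expect_equal(classifyTriadForm(closed2, triads(comp2)[[1]]), "closed")
  disp <- buildIdealG4("4d", triad_form = "none", cations = FALSE)
  expect_equal(classifyTriadForm(G4Structure(within(atoms(disp), {
    x <- x * 10; y <- y * 10; z <- z * 10
  })), triads(comp4)[[1]]), "none")
})

test_that("slip codes parse labels and reject malformed ones", {
  expect_equal(nrow(slipCode("native")@moves), 0)
  expect_equal(slipCode("24d")@moves$column, c(2L, 4L))
  expect_equal(slipCode("2d3u")@moves$dir, c("d", "u"))
  expect_error(slipCode("5d"), "unknown slip code")
  expect_error(slipCode("2x"), "unknown slip code")
})
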