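test_that("squared distances follow the two conventions", {
  expect_identical(distanceMatrix(c(a = "H1", b = "H1"))["a", "b"], 0)
  expect_identical(distanceMatrix(c(a = "H1", b = "H2"))["a", "b"], 1)
  d <- distanceMatrix(c(a = "ACGT", b = "AGGA"), mode = "nt_differences")
  expect_identical(d["a", "b"], 4)       # 2 differences, squared
  dm <- distanceMatrix(c(a = "ACGT", b = "ANGT"), mode = "nt_differences")
  expect_identical(dm["a", "b"], 0)      # missing ignored
  expect_error(distanceMatrix(c(a = "ACGT", b = "ACG"),
                              mode = "nt_differences"), "align")
})

test_that("the survey design reproduces its analytical variance partition", {
  sim <- paperSim()
  h <- collapseHaplotypes(sim$bundle)
  d2 <- distanceMatrix(haplotypeAssignments(h))
  pops <- populations(sim$bundle)[rownames(d2)]
  res <- amova(d2, pops, groups = groupMap(sim$bundle), nPerm = 0)

  # independently derived from the definitional pair-sum formulas
  oracle <- oracleAmova(d2, as.character(pops),
                        groupMap(sim$bundle))
  expect_equal(unname(sumsOfSquares(res)), oracle$ss, tolerance = 1e-12)
  expect_equal(unname(degreesOfFreedom(res)), oracle$df)
  expect_equal(unname(varianceComponents(res)), unname(oracle$v),
               tolerance = 1e-12)
  expect_equal(unname(phiStatistics(res)), unname(oracle$phi),
               tolerance = 1e-12)

  expect_equal(unname(sumsOfSquares(res)),
               c(1200 / 65 - 15, 15, 0, 1200 / 65), tolerance = 1e-12)
  expect_equal(unname(varianceComponents(res)), c(1 / 6, 1 / 3, 0),
               tolerance = 1e-12)
  expect_equal(unname(phiStatistics(res)), c(1 / 3, 1, 1), tolerance = 1e-12)
})

test_that("random unbalanced designs match the pair-sum oracle", {
  set.seed(23)
  for (rep in 1:5) {
    nPops <- sample(4:6, 1)
    sizes <- sample(3:7, nPops, TRUE)
    pop <- rep(paste0("P", seq_len(nPops)), sizes)
    ids <- paste0("i", seq_along(pop))
    grpOfPop <- stats::setNames(
      sample(c("G1", "G2"), nPops, TRUE), paste0("P", seq_len(nPops)))
    grpOfPop[1] <- "G1"; grpOfPop[2] <- "G2"
    hap <- sample(paste0("h", 1:3), length(pop), TRUE)
    d2 <- distanceMatrix(stats::setNames(hap, ids))
    res <- amova(d2, stats::setNames(pop, ids), groups = grpOfPop, nPerm = 0)
    oracle <- oracleAmova(d2, pop, grpOfPop)
    expect_equal(unname(sumsOfSquares(res)), oracle$ss, tolerance = 1e-9)
    expect_equal(unname(varianceComponents(res)), unname(oracle$v),
                 tolerance = 1e-9)
    expect_equal(unname(phiStatistics(res)), unname(oracle$phi),
                 tolerance = 1e-9)
    # additivity of the partition
    ss <- sumsOfSquares(res)
    expect_lt(abs(sum(ss[1:3]) - ss[["total"]]), 1e-9)
  }
})

test_that("a single group reduces to the one-level analysis", {
  set.seed(3)
  pop <- rep(c("P1", "P2", "P3"), c(4, 5, 3))
  ids <- paste0("i", seq_along(pop))
  hap <- sample(c("h1", "h2"), length(pop), TRUE)
  d2 <- distanceMatrix(stats::setNames(hap, ids))
  one <- amova(d2, stats::setNames(pop, ids),
               groups = c(P1 = "G", P2 = "G", P3 = "G"), nPerm = 0)
  expect_true(is.na(phiStatistics(one)[["phiCT"]]))
  expect_identical(phiStatistics(one)[["phiST"]],
                   phiStatistics(one)[["phiSC"]])
  none <- amova(d2, stats::setNames(pop, ids), groups = NULL, nPerm = 0)
  expect_equal(phiStatistics(none)[["phiST"]],
               phiStatistics(one)[["phiST"]], tolerance = 1e-12)
})

test_that("permutation p-values are seeded and order-invariant", {
  sim <- paperSim()
  h <- collapseHaplotypes(sim$bundle)
  d2 <- distanceMatrix(haplotypeAssignments(h))
  pops <- populations(sim$bundle)[rownames(d2)]
  a <- amova(d2, pops, groupMap(sim$bundle), nPerm = 100, seed = 99)
  b <- amova(d2, pops, groupMap(sim$bundle), nPerm = 100, seed = 99)
  expect_identical(amovaPValues(a), amovaPValues(b))

  prm <- sample(rownames(d2))
  c_ <- amova(d2[prm, prm], pops[prm], groupMap(sim$bundle),
              nPerm = 100, seed = 99)
  expect_equal(phiStatistics(c_), phiStatistics(a), tolerance = 1e-12)
  expect_equal(unname(sumsOfSquares(c_)), unname(sumsOfSquares(a)),
               tolerance = 1e-12)
})

test_that("PhiST is 1 exactly when populations are internally monomorphic", {
  ids <- paste0("i", 1:12)
  pop <- stats::setNames(rep(c("P1", "P2", "P3"), each = 4), ids)
  mono <- stats::setNames(rep(c("h1", "h2", "h3"), each = 4), ids)
  res <- amova(distanceMatrix(mono), pop, nPerm = 0)
  expect_identical(phiStatistics(res)[["phiST"]], 1)
  expect_identical(sumsOfSquares(res)[["within_populations"]], 0)

  mixed <- mono
  mixed[1] <- "h2"
  res2 <- amova(distanceMatrix(mixed), pop, nPerm = 0)
  expect_lt(phiStatistics(res2)[["phiST"]], 1)
  expect_gt(sumsOfSquares(res2)[["within_populations"]], 0)
})

test_that("degenerate data yield zero partitions and undefined Phi", {
  ids <- paste0("i", 1:8)
  pop <- stats::setNames(rep(c("P1", "P2"), each = 4), ids)
  res <- amova(distanceMatrix(stats::setNames(rep("h1", 8), ids)),
               pop, groups = c(P1 = "G1", P2 = "G2"), nPerm = 50, seed = 1)
  expect_true(all(sumsOfSquares(res) == 0))
  expect_true(all(is.na(phiStatistics(res))))
  expect_true(all(is.na(amovaPValues(res))))
})

test_that("the AMOVA table mirrors the standard columns", {
  sim <- paperSim()
  h <- collapseHaplotypes(sim$bundle)
  d2 <- distanceMatrix(haplotypeAssignments(h))
  res <- amova(d2, populations(sim$bundle)[rownames(d2)],
               groupMap(sim$bundle), nPerm = 0)
  tab <- amovaTable(res)
  expect_identical(tab$source, c("Among groups", "Among populations",
                                 "Within populations", "Total"))
  expect_equal(tab$df, c(1, 3, 60, 64))
  expect_equal(tab$variance_component[4], 0.5, tolerance = 1e-9)
})
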