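test_that("transition matrices are stochastic and reversible", {
  set.seed(17)
  for (rep in 1:5) {
    f <- rgamma(4, 5); f <- f / sum(f)
    m <- phyloModel(runif(1, 0.3, 10), f)
    P <- hkyTransitionProb(m, runif(1, 0, 3))
    expect_equal(unname(rowSums(P)), rep(1, 4), tolerance = 1e-12)
    flux <- f * P
    expect_lt(max(abs(flux - t(flux))), 1e-12)
    # unit mean rate: -sum(pi_i Q_ii) == 1
    Q <- hkyRateMatrix(m)
    expect_equal(sum(f * -diag(Q)), 1, tolerance = 1e-12)
  }
})

test_that("kappa = 1 with equal frequencies equals the JC69 closed form", {
  m <- phyloModel(1, rep(0.25, 4))
  for (t in c(0, 1e-4, 0.05, 0.3, 1, 4)) {
    tr <- ape::read.tree(text = sprintf("(A:%f,B:%f);", t / 2, t / 2))
    psame <- 0.25 + 0.75 * exp(-4 * t / 3)
    expect_equal(hky85LogLik(tr, c(A = "A", B = "A"), m),
                 log(0.25 * psame), tolerance = 1e-10)
    if (t > 0)
      expect_equal(hky85LogLik(tr, c(A = "A", B = "G"), m),
                   log(0.25 * (1 - psame) / 3), tolerance = 1e-10)
  }
  # zero-length limit
  tr0 <- ape::read.tree(text = "(A:0,B:0);")
  expect_equal(hky85LogLik(tr0, c(A = "C", B = "C"), m), log(0.25),
               tolerance = 1e-12)
})

test_that("pruning equals exhaustive ancestral-state summation", {
  set.seed(29)
  for (rep in 1:6) {
    n <- sample(3:4, 1)
    tr <- ape::unroot(ape::rtree(n))
    S <- sample(1:5, 1)
    chars <- c("A", "C", "G", "T", "N")
    aln <- vapply(seq_len(n), function(i)
      paste(sample(chars, S, TRUE, prob = c(rep(0.23, 4), 0.08)),
            collapse = ""), character(1))
    names(aln) <- tr$tip.label
    kappa <- runif(1, 0.5, 8)
    f <- rgamma(4, 5); f <- f / sum(f)
    expect_equal(hky85LogLik(tr, aln, phyloModel(kappa, f)),
                 oracleLogLik(tr, aln, kappa, f), tolerance = 1e-8)
  }
})

test_that("the likelihood is invariant to leaf order and rerooting", {
  set.seed(31)
  tr <- ape::unroot(ape::rtree(5))
  aln <- as.character(simulateHKYAlignment(tr, 40, kappa = 2, seed = 8))
  m <- phyloModel(2.5, c(0.3, 0.2, 0.3, 0.2))
  ll <- hky85LogLik(tr, aln, m)
  expect_equal(hky85LogLik(tr, aln[rev(names(aln))], m), ll,
               tolerance = 1e-10)
  rr <- ape::unroot(ape::root(tr, outgroup = tr$tip.label[3],
                              resolve.root = FALSE))
  expect_equal(hky85LogLik(rr, aln, m), ll, tolerance = 1e-8)
})

test_that("neighbor joining solves the additive 3-taxon case", {
  d <- matrix(c(0, 2, 3, 2, 0, 3, 3, 3, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- njTree(d)
  bl <- stats::setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(bl[c("A", "B", "C")], c(A = 1, B = 1, C = 2))
  expect_error(njTree(d[1:2, 1:2]), "at least 3")
})

test_that("neighbor joining recovers an ultrametric 4-taxon topology", {
  true <- ape::read.tree(text = "((A:0.1,B:0.1):0.1,(C:0.1,D:0.1):0.1);")
  aln <- simulateHKYAlignment(ape::unroot(true), 800, kappa = 2, seed = 21)
  tr <- njTree(alignmentDistances(aln, "JC69"))
  expect_equal(ape::dist.topo(ape::unroot(true), ape::unroot(tr)), 0,
               ignore_attr = TRUE)
  # identical rows give a star-like tree with zero internal length
  star <- njTree(matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4])))
  expect_true(all(star$edge.length == 0))
})

test_that("the ML search never decreases the likelihood", {
  set.seed(37)
  true <- ape::unroot(ape::rtree(5))
  aln <- simulateHKYAlignment(true, 200, kappa = 3, seed = 5)
  start <- njTree(alignmentDistances(aln, "JC69"))
  freqs <- baseFrequencies(aln)
  startLL <- hky85LogLik(start, aln, phyloModel(4, freqs))
  fit <- mlSearch(aln, start = start)
  expect_gte(treeLogLik(fit), startLL)
  # a second pass from the optimum does not regress
  fit2 <- mlSearch(aln, start = fittedTree(fit))
  expect_gte(treeLogLik(fit2), treeLogLik(fit) - 1e-6)
})

test_that("3-taxon branch lengths match an independent optimizer", {
  skip_if_not_installed("phangorn")
  set.seed(41)
  true <- ape::read.tree(text = "(A:0.15,B:0.25,C:0.4);")
  aln <- simulateHKYAlignment(true, 600, kappa = 3, seed = 13)
  fit <- mlSearch(aln, optimizeKappa = FALSE, kappa = 3)
  pd <- phangorn::phyDat(do.call(rbind, strsplit(as.character(aln), "")))
  f <- baseFrequencies(aln)
  pm <- phangorn::pml(fittedTree(fit), pd, bf = f, Q = c(1, 3, 1, 1, 3, 1))
  opt <- phangorn::optim.pml(pm, optEdge = TRUE,
                             control = phangorn::pml.control(trace = 0))
  expect_equal(treeLogLik(fit), opt$logLik, tolerance = 1e-4)
  mine <- sort(fittedTree(fit)$edge.length)
  theirs <- sort(opt$tree$edge.length)
  expect_equal(mine, theirs, tolerance = 1e-3)
})

test_that("likelihoods agree with an independent implementation", {
  skip_if_not_installed("phangorn")
  set.seed(43)
  tr <- ape::unroot(ape::rtree(6))
  aln <- simulateHKYAlignment(tr, 120, kappa = 2.5,
                              freqs = c(0.35, 0.15, 0.3, 0.2), seed = 3)
  m <- phyloModel(2.5, c(0.35, 0.15, 0.3, 0.2))
  pd <- phangorn::phyDat(do.call(rbind, strsplit(as.character(aln), "")))
  pm <- phangorn::pml(tr, pd, bf = m@freqs, Q = c(1, 2.5, 1, 1, 2.5, 1))
  expect_equal(hky85LogLik(tr, aln, m), pm$logLik, tolerance = 1e-6)
})

test_that("the search recovers a known 6-taxon topology", {
  true <- ape::read.tree(text = paste0(
    "(((A:0.12,B:0.12):0.08,(C:0.12,D:0.12):0.08):0.08,E:0.12,F:0.2);"))
  hits <- 0
  for (s in 1:5) {
    aln <- simulateHKYAlignment(true, 1000, kappa = 3,
                                freqs = c(0.3, 0.2, 0.3, 0.2), seed = 100 + s)
    fit <- mlSearch(aln)
    if (ape::dist.topo(ape::unroot(true), ape::unroot(fittedTree(fit))) == 0)
      hits <- hits + 1
  }
  expect_gte(hits, 5)
})

test_that("an NNI away from the optimum is repaired by the search", {
  true <- ape::read.tree(text = paste0(
    "(((A:0.12,B:0.12):0.08,(C:0.12,D:0.12):0.08):0.08,E:0.12,F:0.2);"))
  aln <- simulateHKYAlignment(true, 1000, kappa = 3, seed = 77)
  # start from a deliberately wrong topology
  wrong <- ape::read.tree(text = paste0(
    "(((A:0.1,C:0.1):0.1,(B:0.1,D:0.1):0.1):0.1,E:0.1,F:0.1);"))
  fit <- mlSearch(aln, start = wrong)
  expect_equal(ape::dist.topo(ape::unroot(true), ape::unroot(fittedTree(fit))),
               0, ignore_attr = TRUE)
})

test_that("bootstrap supports behave at the extremes", {
  true <- ape::read.tree(text = "((A:0.15,B:0.15):0.12,(C:0.15,D:0.15):0.12);")
  aln <- simulateHKYAlignment(ape::unroot(true), 600, kappa = 2, seed = 19)
  one <- bootstrapSupports(aln, nReps = 1, seed = 4)
  expect_true(all(edgeSupports(one) %in% c(0, 1)))
  bs <- bootstrapSupports(aln, nReps = 30, seed = 4, refine = "none")
  expect_gte(max(edgeSupports(bs)), 0.9)   # clean signal: internal edge solid
})
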