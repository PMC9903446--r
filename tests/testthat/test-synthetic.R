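test_that("reference chimera satisfies its structural invariants", {
  ref <- makeReferenceChimera(seed = 3)
  expect_identical(nchar(ref@bAtp6), 619L)
  expect_identical(nchar(ref@ds), 52L)
  expect_identical(nchar(ref@vs), 176L)
  expect_identical(nchar(ref@gsv), 214L)
  full <- chimeraSequence(ref)
  expect_identical(nchar(full), 619L + 52L + 176L + 214L)   # 1061
  expect_identical(substr(full, 1, 9), "GGGCGGGGG")
  expect_identical(substr(full, 658, 671), "GGGGGCGGGACAAA")
  expect_identical(substr(ref@gsv, 1, 3), "ATG")
  expect_identical(substr(ref@gsv, 1, 34), substr(ref@coxiiRef, 1, 34))
  # ORF segment translates without internal stops
  expect_false(grepl("\\*", translateDNA(ref@gsv)))
})

test_that("reference generation is seed-deterministic and length-checked", {
  expect_identical(chimeraSequence(makeReferenceChimera(7)),
                   chimeraSequence(makeReferenceChimera(7)))
  expect_false(chimeraSequence(makeReferenceChimera(7)) ==
                 chimeraSequence(makeReferenceChimera(8)))
  expect_error(makeReferenceChimera(1, gsvLength = 39), "COXII")
  expect_identical(nchar(makeReferenceChimera(1, gsvLength = 240)@gsv), 240L)
})

test_that("haplotype edits apply in reference coordinates", {
  ref <- makeReferenceChimera(seed = 5)
  full <- chimeraSequence(ref)
  expect_identical(applyHaplotypeEdits(ref, list()), full)

  one <- applyHaplotypeEdits(ref, list(snpEdit("vs", 10, "G")))
  expect_identical(nchar(one), nchar(full))
  expect_identical(sum(strsplit(one, "")[[1]] != strsplit(full, "")[[1]]),
                   as.integer(substr(ref@vs, 10, 10) != "G"))

  del <- applyHaplotypeEdits(ref, list(delEdit("vs", 30, 4)))
  expect_identical(nchar(del), nchar(full) - 4L)

  # right-to-left application: a SNP downstream of a deletion still lands at
  # its reference coordinate
  both <- applyHaplotypeEdits(ref, list(delEdit("vs", 30, 4),
                                        snpEdit("vs", 100, "A")))
  pureSnp <- applyHaplotypeEdits(ref, list(snpEdit("vs", 100, "A")))
  expect_identical(substr(both, 619 + 52 + 96, 619 + 52 + 96),
                   substr(pureSnp, 619 + 52 + 100, 619 + 52 + 100))

  expect_error(applyHaplotypeEdits(ref, list(snpEdit("vs", 177))),
               "out of range")
  expect_error(applyHaplotypeEdits(ref, list(delEdit("gsv", 5, 2))),
               "confined")
  expect_identical(
    nchar(applyHaplotypeEdits(ref, list(delEdit("gsv", 5, 2)),
                              restrictIndelsToVs = FALSE)),
    nchar(full) - 2L)
})

test_that("the simulated survey reproduces the design layout with truth", {
  sim <- paperSim()
  b <- sim$bundle
  pos <- chimeraPositive(b)
  expect_identical(sum(pos), 65L)
  chimeras <- as.character(recordSequences(b)[names(pos)[pos]])
  expect_identical(length(unique(chimeras)), 3L)
  # within-population monomorphism
  byPop <- split(chimeras, populations(b)[names(pos)[pos]])
  expect_true(all(vapply(byPop, function(s) length(unique(s)) == 1,
                         logical(1))))
  expect_identical(sim$truth$nHaplotypes, 3L)
  expect_identical(sim$truth$nIndelEvents, 5L)
  expect_identical(sim$truth$nSnpSites, 34L)
  expect_identical(sim$truth$nProteinHaplotypes, 2L)
  # assay-negative populations carry only the conserved atp6 copy
  neg <- names(pos)[!pos]
  expect_true(all(as.character(recordSequences(b)[neg]) ==
                    sim$truth$reference@bAtp6))
  expect_true(all(is.na(sim$truth$haplotypePerRecord[neg])))
})

test_that("a design with no carriers yields no chimera records", {
  d <- paperSurveyDesign(1)
  d@populations$haplotype <- NA_character_
  sim <- simulateSurvey(d)
  expect_identical(sum(chimeraPositive(sim$bundle)), 0L)
})

test_that("seeds move the reference but not the survey layout", {
  a <- paperSim(1)
  b <- paperSim(2)
  expect_identical(dim(a$truth$countsByPopulation),
                   dim(b$truth$countsByPopulation))
  expect_identical(as.vector(a$truth$countsByPopulation),
                   as.vector(b$truth$countsByPopulation))
  expect_false(identical(as.character(recordSequences(a$bundle)[[1]]),
                         as.character(recordSequences(b$bundle)[[1]])))
})

test_that("tree simulation respects limits and seeds", {
  tr <- ape::read.tree(text = "((A:0,B:0):0,C:0,D:0);")
  aln <- simulateHKYAlignment(tr, "ACGTACGT", kappa = 2, seed = 1)
  expect_true(all(as.character(aln) == "ACGTACGT"))

  tr2 <- ape::read.tree(text = "((A:0.2,B:0.2):0.1,C:0.3,D:0.4);")
  a1 <- simulateHKYAlignment(tr2, 300, kappa = 3, seed = 9)
  a2 <- simulateHKYAlignment(tr2, 300, kappa = 3, seed = 9)
  expect_identical(as.character(a1), as.character(a2))
  expect_error(simulateHKYAlignment(tr2, 10, freqs = c(0.5, 0.5, 0.1, 0.1)),
               "sum")
})

test_that("kappa = 1 with equal frequencies behaves like Jukes-Cantor", {
  # two long branches: among observed differences, transitions should make
  # up about 1/3 (2 of the 6 unordered substitution types are transitions)
  tr <- ape::read.tree(text = "(A:1.5,B:1.5);")
  aln <- simulateHKYAlignment(tr, 20000, kappa = 1, seed = 11)
  m <- do.call(rbind, strsplit(as.character(aln), ""))
  diffs <- m[1, ] != m[2, ]
  pair <- paste0(pmin(m[1, diffs], m[2, diffs]), pmax(m[1, diffs], m[2, diffs]))
  tiFrac <- mean(pair %in% c("AG", "CT"))
  expect_lt(abs(tiFrac - 1 / 3), 0.02)
})
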