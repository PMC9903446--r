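test_that("annotation recovers exact planted boundaries on the reference", {
  ref <- makeReferenceChimera(seed = 1)
  ann <- annotateStructure(chimeraSequence(ref), referenceSegments(ref))
  segs <- segmentRanges(ann)
  expect_identical(names(segs), c("b_atp6", "ds", "vs", "gsv"))
  expect_identical(unname(IRanges::start(segs)), c(1L, 620L, 672L, 848L))
  expect_identical(unname(IRanges::end(segs)), c(619L, 671L, 847L, 1061L))
  expect_length(missingSegments(ann), 0)
  expect_identical(ann@coxiiPrefixLen, 34L)
})

test_that("annotation reports missing segments for partial queries", {
  ref <- makeReferenceChimera(seed = 1)
  ann <- annotateStructure(ref@bAtp6, referenceSegments(ref))
  expect_identical(names(segmentRanges(ann)), "b_atp6")
  expect_setequal(missingSegments(ann), c("ds", "vs", "gsv"))
})

test_that("annotation tracks a variable-spacer deletion", {
  ref <- makeReferenceChimera(seed = 2)
  q <- applyHaplotypeEdits(ref, list(delEdit("vs", 50, 4)))
  ann <- annotateStructure(q, referenceSegments(ref))
  segs <- segmentRanges(ann)
  expect_identical(unname(IRanges::end(segs["ds"])), 671L)
  expect_identical(unname(IRanges::width(segs["vs"])), 172L)
  expect_identical(unname(IRanges::start(segs["gsv"])), 844L)
})

test_that("annotation recovers planted boundaries on all survey haplotypes", {
  sim <- paperSim()
  ref <- sim$truth$reference
  for (h in names(sim$truth$boundaries)) {
    seqH <- applyHaplotypeEdits(ref, paperHaplotypeSpecs()[[h]])
    ann <- annotateStructure(seqH, referenceSegments(ref))
    b <- sim$truth$boundaries[[h]]
    segs <- segmentRanges(ann)
    expect_identical(unname(IRanges::end(segs["b_atp6"])),
                     as.integer(b[["b_atp6_end"]]))
    expect_identical(unname(IRanges::end(segs["ds"])),
                     as.integer(b[["ds_end"]]))
    expect_identical(unname(IRanges::end(segs["vs"])),
                     as.integer(b[["vs_end"]]))
    expect_identical(unname(IRanges::end(segs["gsv"])),
                     as.integer(b[["gsv_end"]]))
  }
})

test_that("mirror motif scanning finds the junction pair and labels hits", {
  ref <- makeReferenceChimera(seed = 1)
  hits <- findMirrorMotifs(chimeraSequence(ref), "GGGCGGGGG")
  expect_identical(nrow(hits), 2L)
  fwd <- hits[hits$orientation == "forward", ]
  mir <- hits[hits$orientation == "mirror", ]
  expect_identical(c(fwd$start, fwd$end), c(1L, 9L))
  expect_identical(c(mir$start, mir$end), c(658L, 666L))

  expect_identical(nrow(findMirrorMotifs("AAAAAAAA", "GGGCGGGGG")), 0L)
  expect_error(findMirrorMotifs("ACGT", "GGG"), "at least 5")

  # reversal-palindromic motif: forward and mirror hits coincide, reported once
  pal <- findMirrorMotifs("AAGGGGGAA", "GGGGG")
  expect_identical(nrow(pal), 1L)
  expect_identical(pal$orientation, "forward")
})

test_that("mirror motif hits map through reversal of the query", {
  set.seed(5)
  for (rep in 1:5) {
    q <- paste0(randomDnaString(30), "GGGCGGGGG", randomDnaString(20),
                "GGGGGCGGG", randomDnaString(10))
    motif <- "GGGCGGGGG"
    hits <- findMirrorMotifs(q, motif)
    qr <- paste(rev(strsplit(q, "")[[1]]), collapse = "")
    hitsR <- findMirrorMotifs(qr, motif)
    n <- nchar(q)
    mapped <- data.frame(start = n - hits$end + 1L, end = n - hits$start + 1L,
                         orientation = ifelse(hits$orientation == "forward",
                                              "mirror", "forward"))
    mapped <- mapped[order(mapped$start), ]
    expect_identical(hitsR$start, mapped$start)
    expect_identical(hitsR$end, mapped$end)
    expect_identical(hitsR$orientation, mapped$orientation)
  }
})

test_that("variable-spacer catalog counts indel events and SNP sites", {
  expect_error(catalogVsVariation(c(a = "ACGT")), "at least 2")

  same <- catalogVsVariation(c(a = "ACGT", b = "ACGT"))
  expect_identical(indelEvents(same), 0L)
  expect_identical(snpSites(same), 0L)

  indel <- catalogVsVariation(c(a = "AC-GT", b = "ACAGT"))
  expect_identical(indelEvents(indel), 1L)
  expect_identical(snpSites(indel), 0L)
  expect_identical(gapColumns(indel), 1L)

  # a shared gap run counts once; SNP columns exclude gapped columns
  mix <- catalogVsVariation(c(r = "ACGTACGT", s = "AC--ACGA", t = "AC--ACGA"))
  expect_identical(indelEvents(mix), 1L)
  expect_identical(snpSites(mix), 1L)

  sim <- paperSim()
  cat_ <- catalogVsVariation(sim$truth$vsAlignment)
  expect_identical(indelEvents(cat_), sim$truth$nIndelEvents)
  expect_identical(snpSites(cat_), sim$truth$nSnpSites)
  expect_identical(gapColumns(cat_), as.integer(sim$truth$gapColumns))
  # per-haplotype edit lists recompose the counts
  ed <- vsEdits(cat_)
  runs <- unique(do.call(rbind, lapply(ed, function(e)
    e$indels[, c("start", "end")])))
  expect_identical(nrow(runs), sim$truth$nIndelEvents)
  snpCols <- unique(unlist(lapply(ed, function(e) e$snps$column)))
  expect_identical(length(snpCols), as.integer(sim$truth$nSnpSites))
})

test_that("COXII prefix length honors mismatches and missing states", {
  ref <- makeReferenceChimera(seed = 4)
  expect_identical(coxiiPrefixLen(ref@gsv, ref@coxiiRef), 34L)
  expect_identical(coxiiPrefixLen("TTTT", "ATTT"), 0L)
  expect_identical(coxiiPrefixLen("ACGT", "ACGTAA"), 4L)
  expect_identical(coxiiPrefixLen("ACNT", "ACGT"), 2L)
  expect_identical(coxiiPrefixLen("AC?T", "ACGT"), 2L)
})
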