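#' ReferenceChimera: synthetic reference for the chimeric locus
#'
#' Holds the four segments of the chimeric CMS locus: the duplicated
#' mitochondrial atp6 copy (`bAtp6`, 619 bp), its conserved downstream
#' (`ds`, 52 bp), the variable spacer (`vs`, 176 bp) and the ORF segment
#' (`gsv`, configurable length). The junction motif pair GGGCGGGGG /
#' GGGGGCGGG (a mirror repeat: one is the character reversal of the other)
#' is embedded at positions 1-9 and at the 3' end of `ds`, whose last 14
#' bases are GGGGGCGGGACAAA. The first 34 bases of `gsv` are identical to
#' the COXII reference prefix and begin with the ATG start codon.
#'
#' @slot bAtp6,ds,vs,gsv character; the four segments.
#' @slot coxiiRef character; a COXII segment whose first 34 bases match `gsv`
#'   and which then diverges.
#' @exportClass ReferenceChimera
setClass("ReferenceChimera",
  representation(bAtp6 = "character", ds = "character", vs = "character",
                 gsv = "character", coxiiRef = "character")
)

setValidity("ReferenceChimera", function(object) {
  if (nchar(object@bAtp6) != 619) return("bAtp6 must be 619 bp")
  if (nchar(object@ds) != 52) return("ds must be 52 bp")
  if (substr(object@bAtp6, 1, 9) != "GGGCGGGGG")
    return("bAtp6 must start with GGGCGGGGG")
  cons <- paste0(object@bAtp6, object@ds)
  if (substr(cons, 658, 671) != "GGGGGCGGGACAAA")
    return("conserved region must end with GGGGGCGGGACAAA")
  if (nchar(object@gsv) >= 34 &&
      substr(object@gsv, 1, 34) != substr(object@coxiiRef, 1, 34))
    return("first 34 bases of gsv must match the COXII reference")
  TRUE
})

JUNCTION_MOTIF <- "GGGCGGGGG"

.randomDNA <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

.reverseChars <- function(x) paste(rev(strsplit(x, "")[[1]]), collapse = "")

# Random in-frame codons avoiding stop codons, truncated to n bases.
.randomORF <- function(n) {
  stops <- c("TAA", "TAG", "TGA")
  k <- ceiling(n / 3)
  codons <- character(k)
  for (i in seq_len(k)) {
    repeat {
      cd <- .randomDNA(3)
      if (!cd %in% stops) break
    }
    codons[i] <- cd
  }
  substr(paste(codons, collapse = ""), 1, n)
}

#' Generate a synthetic reference chimera
#'
#' Builds a reference sequence for the chimeric locus with the documented
#' anchors (see [ReferenceChimera-class]); all non-motif positions are drawn
#' uniformly from `{A,C,G,T}` (the ORF segment from non-stop codons so it
#' translates without internal stops). The junction motif and its mirror are
#' guaranteed to occur nowhere else in the concatenated sequence. Three ORF
#' codons (14, 17 and 24, when the length allows) are fixed to GAC, CTC and
#' TGC so that haplotype specifications can plant synonymous and
#' nonsynonymous substitutions with known protein consequences.
#'
#' @param seed Integer seed; the same seed yields a byte-identical reference.
#' @param gsvLength ORF segment length in bp (default 214: the surveyed ORF
#'   with the 26 untrimmed bases excluded; >= 40 required so the segment can
#'   host the 34-base COXII prefix).
#' @return A [ReferenceChimera-class].
#' @examples
#' ref <- makeReferenceChimera(seed = 1)
#' nchar(chimeraSequence(ref))  # 619 + 52 + 176 + 214 = 1061
#' @export
makeReferenceChimera <- function(seed = 1L, gsvLength = 214L) {
  if (gsvLength < 40)
    fail("gsvLength must be >= 40 to host the 34-base COXII prefix (got %d)",
         gsvLength)
  withSeed(seed, {
    mirror <- .reverseChars(JUNCTION_MOTIF)
    for (attempt in 1:100) {
      bAtp6 <- paste0(JUNCTION_MOTIF, .randomDNA(619 - 9 - 7), "TGAGTAA")
      ds <- paste0("TTTCATAA", .randomDNA(52 - 8 - 14), "GGGGGCGGGACAAA")
      vs <- .randomDNA(176)
      gsv <- paste0("ATG", .randomORF(gsvLength - 3))
      if (gsvLength >= 72) {
        substr(gsv, 40, 42) <- "GAC"
        substr(gsv, 49, 51) <- "CTC"
        substr(gsv, 70, 72) <- "TGC"
      }
      full <- paste0(bAtp6, ds, vs, gsv)
      fwd <- gregexpr(JUNCTION_MOTIF, full, fixed = TRUE)[[1]]
      rev_ <- gregexpr(mirror, full, fixed = TRUE)[[1]]
      if (identical(as.integer(fwd), 1L) && identical(as.integer(rev_), 658L))
        break
    }
    coxiiTail <- .randomDNA(16)
    if (gsvLength >= 35) {
      alt <- setdiff(c("A", "C", "G", "T"), substr(gsv, 35, 35))
      substr(coxiiTail, 1, 1) <- sample(alt, 1)
    }
    coxiiRef <- paste0(substr(gsv, 1, 34), coxiiTail)
    methods::new("ReferenceChimera", bAtp6 = bAtp6, ds = ds, vs = vs,
                 gsv = gsv, coxiiRef = coxiiRef)
  })
}

#' Full reference chimera sequence
#'
#' @param ref A [ReferenceChimera-class].
#' @return Single character string `bAtp6 + ds + vs + gsv`.
#' @export
chimeraSequence <- function(ref) {
  stopifnot(methods::is(ref, "ReferenceChimera"))
  paste0(ref@bAtp6, ref@ds, ref@vs, ref@gsv)
}

#' Reference segments of a chimera as a DNAStringSet
#'
#' @param ref A [ReferenceChimera-class].
#' @return [Biostrings::DNAStringSet] named `b_atp6`, `ds`, `coxii_prefix`,
#'   `gsv_ref`, suitable for [annotateStructure()].
#' @export
referenceSegments <- function(ref) {
  stopifnot(methods::is(ref, "ReferenceChimera"))
  Biostrings::DNAStringSet(c(b_atp6 = ref@bAtp6, ds = ref@ds,
                             coxii_prefix = ref@coxiiRef, gsv_ref = ref@gsv))
}

# ---- haplotype edits ------------------------------------------------------

#' Haplotype edit constructors
#'
#' Edits are expressed in 1-based coordinates of the *unedited* reference
#' segment they target (`"vs"`, `"gsv"`, `"b_atp6"` or `"ds"`). `snpEdit`
#' substitutes one base (default: the transition partner of the reference
#' base), `delEdit` deletes `len` bases starting at `pos`, and `insEdit`
#' inserts `seq` immediately after `pos`.
#'
#' @param segment Segment name.
#' @param pos 1-based position within the segment.
#' @param alt Substituted base, or `NULL` for the transition partner.
#' @param len Deletion length.
#' @param seq Inserted bases.
#' @return A list describing one edit.
#' @name haplotypeEdits
NULL

#' @rdname haplotypeEdits
#' @export
snpEdit <- function(segment, pos, alt = NULL)
  list(op = "snp", segment = segment, pos = as.integer(pos), alt = alt)

#' @rdname haplotypeEdits
#' @export
delEdit <- function(segment, pos, len)
  list(op = "del", segment = segment, pos = as.integer(pos), len = as.integer(len))

#' @rdname haplotypeEdits
#' @export
insEdit <- function(segment, pos, seq)
  list(op = "ins", segment = segment, pos = as.integer(pos), seq = toupper(seq))

.transitionPartner <- function(base) chartr("ACGT", "GTAC", base)

.segmentOffsets <- function(ref) {
  lens <- c(b_atp6 = nchar(ref@bAtp6), ds = nchar(ref@ds),
            vs = nchar(ref@vs), gsv = nchar(ref@gsv))
  offs <- c(0, cumsum(lens))[1:4]
  names(offs) <- names(lens)
  list(offsets = offs, lengths = lens)
}

#' Apply haplotype edits to a reference chimera
#'
#' Edits are applied right-to-left so that every position refers to the
#' unedited reference. Indels are confined to the variable spacer unless
#' `restrictIndelsToVs = FALSE`.
#'
#' @param ref A [ReferenceChimera-class].
#' @param edits List of edits from [snpEdit()], [delEdit()], [insEdit()].
#' @param restrictIndelsToVs Reject indels outside the `vs` segment.
#' @return Character string: the full edited chimera sequence.
#' @export
applyHaplotypeEdits <- function(ref, edits, restrictIndelsToVs = TRUE) {
  stopifnot(methods::is(ref, "ReferenceChimera"))
  seg <- .segmentOffsets(ref)
  full <- chimeraSequence(ref)
  if (!length(edits)) return(full)
  glob <- lapply(edits, function(e) {
    if (!e$segment %in% names(seg$offsets))
      fail("unknown segment '%s'", e$segment)
    segLen <- seg$lengths[[e$segment]]
    endPos <- if (identical(e$op, "del")) e$pos + e$len - 1L else e$pos
    if (e$pos < 1 || endPos > segLen)
      fail("edit position %d out of range for segment %s (length %d)",
           e$pos, e$segment, segLen)
    if (e$op %in% c("del", "ins") && restrictIndelsToVs && e$segment != "vs")
      fail("indels are confined to the vs segment (got one in %s)", e$segment)
    e$gpos <- as.integer(seg$offsets[[e$segment]] + e$pos)
    e
  })
  glob <- glob[order(vapply(glob, `[[`, integer(1), "gpos"), decreasing = TRUE)]
  chars <- strsplit(full, "")[[1]]
  for (e in glob) {
    if (e$op == "snp") {
      alt <- if (is.null(e$alt)) .transitionPartner(chars[e$gpos]) else toupper(e$alt)
      chars[e$gpos] <- alt
    } else if (e$op == "del") {
      chars <- chars[-(e$gpos:(e$gpos + e$len - 1L))]
    } else if (e$op == "ins") {
      chars <- append(chars, strsplit(e$seq, "")[[1]], after = e$gpos)
    } else fail("unknown edit op '%s'", e$op)
  }
  paste(chars, collapse = "")
}

# ---- survey design --------------------------------------------------------

#' SurveyDesign: layout of a simulated survey
#'
#' @slot populations data.frame with columns `code`, `nCollected`,
#'   `nSequenced`, `haplotype` (NA for populations not carrying the chimera)
#'   and `group` (NA outside the AMOVA design).
#' @slot haplotypeSpecs named list of edit lists (see [haplotypeEdits]); one
#'   entry per haplotype label, the reference haplotype having no edits.
#' @slot seed integer.
#' @exportClass SurveyDesign
setClass("SurveyDesign",
  representation(populations = "data.frame", haplotypeSpecs = "list",
                 seed = "integer")
)

setValidity("SurveyDesign", function(object) {
  p <- object@populations
  need <- c("code", "nCollected", "nSequenced", "haplotype", "group")
  if (!all(need %in% colnames(p)))
    return(paste("populations needs columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(p$code)) return("population codes must be unique")
  if (any(p$nSequenced > p$nCollected))
    return("nSequenced must not exceed nCollected")
  carriers <- !is.na(p$haplotype)
  if (any(!p$haplotype[carriers] %in% names(object@haplotypeSpecs)))
    return("every carrier haplotype needs a haplotypeSpecs entry")
  TRUE
})

#' The surveyed-population design of the wild-rice study
#'
#' Seventeen populations; five of them (PS, GZ, TL, HK, YJ) carry the
#' chimeric locus, with sequenced subsets of 15/15/15/15/5 individuals
#' bearing haplotypes H1/H1/H2/H2/H3 respectively. The AMOVA grouping places
#' YJ alone in group G1 and the other four carriers in G2. Haplotype H2 is
#' the reference (identical to the reference chimera); H1 and H3 carry fixed
#' variable-spacer edit sets totalling 5 indel events and 34 SNP sites, plus
#' one synonymous ORF substitution (H1) and two nonsynonymous ones (H3), so
#' the three nucleotide haplotypes collapse to two protein haplotypes.
#'
#' @param seed Integer seed stored in the design.
#' @return A [SurveyDesign-class].
#' @export
paperSurveyDesign <- function(seed = 1L) {
  codes <- c("NHNC", "WN", "QH", "HK", "YJ", "NN", "LB", "XZ", "HZ", "GP",
             "YL", "FC", "BH", "GZ", "PS", "TL", "DX")
  collected <- c(15, 25, 25, 25, 5, 20, 30, 30, 30, 30, 30, 30, 27, 30, 25, 26, 24)
  hap <- rep(NA_character_, length(codes))
  hap[match(c("PS", "GZ"), codes)] <- "H1"
  hap[match(c("TL", "HK"), codes)] <- "H2"
  hap[match("YJ", codes)] <- "H3"
  grp <- rep(NA_character_, length(codes))
  grp[match("YJ", codes)] <- "G1"
  grp[match(c("PS", "GZ", "TL", "HK"), codes)] <- "G2"
  pops <- data.frame(code = codes, nCollected = collected,
                     nSequenced = pmin(15L, collected), haplotype = hap,
                     group = grp, stringsAsFactors = FALSE)
  methods::new("SurveyDesign", populations = pops,
               haplotypeSpecs = paperHaplotypeSpecs(), seed = as.integer(seed))
}

#' Fixed haplotype edit sets of the emulated survey
#'
#' @return Named list of edit lists for haplotypes H1, H2 (reference, empty)
#'   and H3. Across H1 and H3 the variable spacer carries 5 distinct indel
#'   events (two in H1, three in H3) and 34 SNP sites (16 + 18, disjoint,
#'   all outside every deletion), matching the "five indels, more than 30
#'   SNPs" character of the spacer.
#' @export
paperHaplotypeSpecs <- function() {
  h1snps <- c(5, 9, 13, 33, 37, 41, 45, 49, 77, 81, 85, 101, 105, 109, 113, 117)
  h3snps <- c(7, 11, 15, 35, 39, 43, 47, 51, 79, 83, 87, 103, 107, 111, 115,
              119, 123, 127)
  h1 <- c(lapply(h1snps, function(p) snpEdit("vs", p)),
          list(delEdit("vs", 21, 4), insEdit("vs", 60, "TCA"),
               snpEdit("gsv", 51)))          # CTC -> CTT, synonymous (Leu)
  h3 <- c(lapply(h3snps, function(p) snpEdit("vs", p)),
          list(delEdit("vs", 91, 2), delEdit("vs", 131, 5),
               insEdit("vs", 150, "GT"),
               snpEdit("gsv", 40),           # GAC -> AAC, Asp -> Asn
               snpEdit("gsv", 70)))          # TGC -> CGC, Cys -> Arg
  list(H1 = h1, H2 = list(), H3 = h3)
}

# ---- ground-truth VS alignment -------------------------------------------

# Build the true gapped alignment of the variable spacer across haplotypes
# from their edit lists. Requires indel footprints (deletion ranges,
# insertion anchors) to be mutually non-overlapping across haplotypes.
.buildVsAlignment <- function(refVs, specs) {
  L <- nchar(refVs)
  refChars <- strsplit(refVs, "")[[1]]
  parse <- lapply(specs, function(edits) {
    edits <- Filter(function(e) e$segment == "vs", edits)
    list(
      snp = Filter(function(e) e$op == "snp", edits),
      del = Filter(function(e) e$op == "del", edits),
      ins = Filter(function(e) e$op == "ins", edits)
    )
  })
  delRanges <- do.call(rbind, unlist(lapply(names(parse), function(h)
    lapply(parse[[h]]$del, function(e)
      data.frame(hap = h, start = e$pos, end = e$pos + e$len - 1L))),
    recursive = FALSE))
  if (!is.null(delRanges) && nrow(delRanges) > 1) {
    o <- order(delRanges$start)
    dr <- delRanges[o, ]
    if (any(dr$start[-1] <= dr$end[-nrow(dr)]))
      fail("deletion ranges overlap across haplotypes; true alignment undefined")
  }
  insAnchors <- unlist(lapply(parse, function(p)
    vapply(p$ins, `[[`, integer(1), "pos")))
  if (anyDuplicated(insAnchors))
    fail("insertions share an anchor position; true alignment undefined")
  haps <- names(specs)
  # columns: one per reference position, plus insertion blocks after anchors
  cols <- lapply(0:L, function(p) {
    out <- list()
    if (p > 0) out <- list(list(type = "ref", pos = p))
    for (h in haps) for (e in parse[[h]]$ins) if (e$pos == p) {
      for (ch in strsplit(e$seq, "")[[1]])
        out <- c(out, list(list(type = "ins", hap = h, char = ch)))
    }
    out
  })
  cols <- unlist(cols, recursive = FALSE)
  m <- matrix("", nrow = length(haps), ncol = length(cols),
              dimnames = list(haps, NULL))
  for (h in haps) {
    snpAt <- stats::setNames(
      vapply(parse[[h]]$snp, function(e)
        if (is.null(e$alt)) .transitionPartner(refChars[e$pos]) else e$alt,
        character(1)),
      vapply(parse[[h]]$snp, `[[`, integer(1), "pos"))
    delMask <- rep(FALSE, L)
    for (e in parse[[h]]$del) delMask[e$pos:(e$pos + e$len - 1L)] <- TRUE
    for (j in seq_along(cols)) {
      cl <- cols[[j]]
      m[h, j] <- if (cl$type == "ref") {
        if (delMask[cl$pos]) "-"
        else if (as.character(cl$pos) %in% names(snpAt)) snpAt[[as.character(cl$pos)]]
        else refChars[cl$pos]
      } else {
        if (identical(cl$hap, h)) cl$char else "-"
      }
    }
  }
  m
}

# ---- survey simulation ----------------------------------------------------

#' Simulate a survey dataset with ground truth
#'
#' Emits `nSequenced` records per carrier population, all identical within a
#' population (each population is fixed for a single haplotype, as in the
#' emulated survey). Populations not carrying the chimeric locus contribute
#' records holding only the conserved atp6 copy, flagged assay-negative for
#' the chimera amplification; their absence of the locus is data, not an
#' error. Ground truth includes the haplotype of every record, the planted
#' segment boundaries per haplotype, the true gapped variable-spacer
#' alignment and its indel/SNP counts, the ORF variant per haplotype, and
#' the expected number of distinct protein haplotypes.
#'
#' @param design A [SurveyDesign-class], e.g. [paperSurveyDesign()].
#' @param ref A [ReferenceChimera-class]; defaults to
#'   `makeReferenceChimera(design@seed)`.
#' @return List with elements `bundle` (a [SurveyBundle-class]) and `truth`.
#' @export
simulateSurvey <- function(design, ref = makeReferenceChimera(design@seed)) {
  stopifnot(methods::is(design, "SurveyDesign"))
  methods::validObject(design)
  pops <- design@populations
  specs <- design@haplotypeSpecs
  seg <- .segmentOffsets(ref)
  hapSeq <- vapply(specs, function(e) applyHaplotypeEdits(ref, e), character(1))
  ids <- character(0); seqs <- character(0); pop <- character(0)
  positive <- logical(0); trueHap <- character(0)
  for (i in seq_len(nrow(pops))) {
    p <- pops[i, ]
    if (p$nSequenced == 0) next
    recIds <- sprintf("%s_%02d", p$code, seq_len(p$nSequenced))
    carrier <- !is.na(p$haplotype)
    s <- if (carrier) hapSeq[[p$haplotype]] else ref@bAtp6
    ids <- c(ids, recIds)
    seqs <- c(seqs, rep(s, p$nSequenced))
    pop <- c(pop, rep(p$code, p$nSequenced))
    positive <- c(positive, rep(carrier, p$nSequenced))
    trueHap <- c(trueHap, rep(if (carrier) p$haplotype else NA_character_,
                              p$nSequenced))
  }
  dna <- Biostrings::DNAStringSet(seqs); names(dna) <- ids
  names(pop) <- ids; names(positive) <- ids; names(trueHap) <- ids
  grpRows <- !is.na(pops$group)
  groupMap <- stats::setNames(pops$group[grpRows], pops$code[grpRows])
  bundle <- methods::new("SurveyBundle", sequences = dna, population = pop,
                         groupMap = groupMap,
                         references = referenceSegments(ref),
                         chimeraPositive = positive)
  # planted boundaries per haplotype (1-based inclusive, on the edited seq)
  boundaries <- lapply(names(specs), function(h) {
    vsDelta <- sum(vapply(specs[[h]], function(e) {
      if (e$segment != "vs") return(0L)
      switch(e$op, del = -e$len, ins = nchar(e$seq), 0L)
    }, integer(1)))
    bEnd <- seg$lengths[["b_atp6"]]
    dsEnd <- bEnd + seg$lengths[["ds"]]
    vsEnd <- dsEnd + seg$lengths[["vs"]] + vsDelta
    gsvEnd <- vsEnd + seg$lengths[["gsv"]]
    c(b_atp6_end = bEnd, ds_end = dsEnd, vs_end = vsEnd, gsv_end = gsvEnd)
  })
  names(boundaries) <- names(specs)
  vsAln <- .buildVsAlignment(ref@vs, specs)
  gapRuns <- unique(do.call(rbind, lapply(rownames(vsAln), function(h) {
    r <- rle(vsAln[h, ] == "-")
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    data.frame(start = starts[r$values], end = ends[r$values])
  })))
  gapCols <- colSums(vsAln == "-") > 0
  snpCols <- vapply(seq_len(ncol(vsAln)), function(j) {
    col <- vsAln[, j]
    !any(col == "-") && length(unique(col[!col %in% .MISSING_CHARS])) >= 2
  }, logical(1))
  gsvSet <- vapply(names(specs), function(h) {
    b <- boundaries[[h]]
    substr(hapSeq[[h]], b[["vs_end"]] + 1L, b[["gsv_end"]])
  }, character(1))
  counts <- table(factor(trueHap[positive]),
                  factor(pop[positive], levels = unique(pop[positive])))
  truth <- list(
    haplotypePerRecord = trueHap,
    nHaplotypes = length(unique(trueHap[positive])),
    countsByPopulation = counts,
    boundaries = boundaries,
    vsAlignment = vsAln,
    nIndelEvents = if (is.null(gapRuns)) 0L else nrow(gapRuns),
    nSnpSites = sum(snpCols),
    gapColumns = sum(gapCols),
    gsvByHaplotype = gsvSet,
    nProteinHaplotypes = length(unique(vapply(gsvSet, translateDNA,
                                              character(1)))),
    reference = ref
  )
  list(bundle = bundle, truth = truth)
}

# ---- sequence evolution on a tree ----------------------------------------

#' Simulate sequence evolution along a tree under HKY85
#'
#' Site-independent simulation of a root sequence down a tree under the
#' HKY85 substitution model, with branch lengths in expected substitutions
#' per site (the rate matrix is scaled to unit mean rate).
#'
#' @param tree A `phylo` object with nonnegative branch lengths.
#' @param rootSeq Character string over `{A,C,G,T}` used as the root state,
#'   or a single integer length to draw the root from the base frequencies.
#' @param kappa Transition/transversion rate ratio.
#' @param freqs Base frequencies (A, C, G, T); must sum to 1.
#' @param seed Integer seed (same seed, same alignment) or `NULL`.
#' @return [Biostrings::DNAStringSet] with one sequence per tip label.
#' @export
simulateHKYAlignment <- function(tree, rootSeq, kappa = 4, freqs = rep(0.25, 4),
                                 seed = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (any(tree$edge.length < 0)) fail("branch lengths must be >= 0")
  if (length(freqs) != 4 || any(freqs <= 0) || abs(sum(freqs) - 1) > 1e-9)
    fail("freqs must be 4 positive values summing to 1")
  model <- phyloModel(kappa, freqs)
  eig <- .hkyEigen(model)
  bases <- c("A", "C", "G", "T")
  withSeed(seed, {
    root <- if (is.numeric(rootSeq) && length(rootSeq) == 1) {
      sample.int(4, rootSeq, replace = TRUE, prob = freqs)
    } else {
      x <- match(strsplit(toupper(as.character(rootSeq)), "")[[1]], bases)
      if (anyNA(x)) fail("rootSeq must contain only A, C, G, T")
      x
    }
    nTip <- length(tree$tip.label)
    phy <- stats::reorder(tree, "postorder")
    E <- phy$edge; el <- phy$edge.length
    states <- vector("list", nTip + phy$Nnode)
    states[[nTip + 1L]] <- root
    for (i in rev(seq_len(nrow(E)))) {      # preorder: parents before children
      P <- .hkyProb(eig, el[i])
      par <- states[[E[i, 1]]]
      ch <- integer(length(par))
      for (s in 1:4) {
        idx <- which(par == s)
        if (length(idx))
          ch[idx] <- sample.int(4, length(idx), replace = TRUE, prob = P[s, ])
      }
      states[[E[i, 2]]] <- ch
    }
    out <- vapply(seq_len(nTip), function(i)
      paste(bases[states[[i]]], collapse = ""), character(1))
    names(out) <- phy$tip.label
    Biostrings::DNAStringSet(out)
  })
}
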