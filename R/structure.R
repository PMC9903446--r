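#' Annotate the chimeric architecture of a query sequence
#'
#' Locates the conserved anchor segments (`b_atp6`, then `ds` downstream of
#' it) by semi-global (glocal) alignment of each reference against the query,
#' using the same alignment engine and default scoring as
#' [identityPercent()]. A segment counts as found when its alignment identity
#' is at least `minAnchorIdentity`. The ORF segment (`gsv`) is located by
#' semi-global alignment of `gsv_ref` when present, else as the first ATG at
#' or after the COXII-prefix match; the variable spacer (`vs`) is the
#' interval between the `ds` end and the `gsv` start. Anchors that cannot be
#' located are reported as missing segments, not errors: sequences that
#' legitimately lack the chimeric locus (assay-negative individuals) pass
#' through the same annotator.
#'
#' @param query Query sequence (character or [Biostrings::DNAString]).
#' @param refs Named reference segments ([Biostrings::DNAStringSet] or named
#'   character) containing at least `b_atp6` and `ds`; optionally
#'   `coxii_prefix` and `gsv_ref`.
#' @param minAnchorIdentity Minimum alignment identity (fraction) for an
#'   anchor to count as found (default 0.95).
#' @return A [StructureAnnotation-class] with 1-based inclusive segment
#'   coordinates, junction-motif hits, the COXII prefix length (when
#'   assessable) and notes on unannotated flanks.
#' @export
annotateStructure <- function(query, refs, minAnchorIdentity = 0.95) {
  query <- normalizeSequence(as.character(query), "query")
  if (methods::is(refs, "XStringSet")) refs <- as.character(refs)
  refs <- unlist(as.list(refs))
  if (!all(c("b_atp6", "ds") %in% names(refs)))
    fail("refs must contain b_atp6 and ds")
  qlen <- nchar(query)
  found <- list()
  missing <- character(0)
  notes <- character(0)

  locate <- function(refSeq, from) {
    sub <- substr(query, from, qlen)
    if (nchar(sub) < 1) return(NULL)
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(refSeq), Biostrings::DNAString(sub),
      type = "global-local",
      substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
        match = 1, mismatch = -1, baseOnly = FALSE),
      gapOpening = 0, gapExtension = 2)
    p <- as.character(Biostrings::alignedPattern(pa))
    s <- as.character(Biostrings::alignedSubject(pa))
    ident <- sum(strsplit(p, "")[[1]] == strsplit(s, "")[[1]] &
                   strsplit(p, "")[[1]] != "-") / nchar(p)
    if (ident < minAnchorIdentity) return(NULL)
    st <- IRanges::start(Biostrings::subject(pa)) + from - 1L
    en <- IRanges::end(Biostrings::subject(pa)) + from - 1L
    list(start = st, end = en, identity = ident)
  }

  b <- locate(refs[["b_atp6"]], 1L)
  if (is.null(b)) missing <- c(missing, "b_atp6") else found$b_atp6 <- b
  dsFrom <- if (!is.null(b)) b$end + 1L else 1L
  d <- if (dsFrom <= qlen) locate(refs[["ds"]], dsFrom) else NULL
  if (is.null(d)) missing <- c(missing, "ds") else found$ds <- d

  gsvStart <- NA_integer_
  if (!is.null(d)) {
    after <- d$end + 1L
    if (after <= qlen) {
      if ("gsv_ref" %in% names(refs)) {
        g <- locate(refs[["gsv_ref"]], after)
        if (!is.null(g)) gsvStart <- g$start
      }
      if (is.na(gsvStart) && "coxii_prefix" %in% names(refs)) {
        prefix <- substr(refs[["coxii_prefix"]], 1, 34)
        cx <- locate(prefix, after)
        if (!is.null(cx)) {
          atg <- regexpr("ATG", substr(query, cx$start, qlen), fixed = TRUE)
          if (atg > 0) gsvStart <- cx$start + as.integer(atg) - 1L
        }
      }
    }
  }
  if (is.na(gsvStart)) {
    missing <- c(missing, "gsv", "vs")
  } else {
    found$gsv <- list(start = gsvStart, end = qlen)
    if (!is.null(d) && gsvStart > d$end + 1L) {
      found$vs <- list(start = d$end + 1L, end = gsvStart - 1L)
    } else {
      missing <- c(missing, "vs")
    }
  }
  segOrder <- intersect(c("b_atp6", "ds", "vs", "gsv"), names(found))
  segs <- IRanges::IRanges(
    start = vapply(found[segOrder], `[[`, numeric(1), "start"),
    end = vapply(found[segOrder], `[[`, numeric(1), "end"),
    names = segOrder)
  if (!is.null(b) && b$start > 1)
    notes <- c(notes, sprintf("unannotated 5' flank of %d bp", b$start - 1L))
  if (is.na(gsvStart) && !is.null(d) && d$end < qlen)
    notes <- c(notes, sprintf("unannotated 3' region of %d bp after ds",
                              qlen - d$end))
  prefixLen <- NA_integer_
  if (!is.na(gsvStart) && "coxii_prefix" %in% names(refs))
    prefixLen <- coxiiPrefixLen(substr(query, gsvStart, qlen),
                                refs[["coxii_prefix"]])
  methods::new("StructureAnnotation",
               segments = segs, missingSegments = missing,
               motifHits = findMirrorMotifs(query, JUNCTION_MOTIF),
               coxiiPrefixLen = as.integer(prefixLen), notes = notes)
}

#' Find a motif and its mirror (character-reversal) in a sequence
#'
#' Reports all exact occurrences of `motif` and of its character reversal
#' (NOT the reverse complement: the junction pair GGGCGGGGG / GGGGGCGGG of
#' the chimeric locus is a mirror pair, like 123456789 / 987654321). Hits
#' are labeled `"forward"` or `"mirror"`; when the motif equals its own
#' reversal the duplicated hits are reported once, as forward.
#'
#' @param query Sequence (character or [Biostrings::DNAString]).
#' @param motif Motif of length >= 5.
#' @return data.frame with columns `motif`, `start`, `end`, `orientation`,
#'   1-based inclusive, sorted by start.
#' @export
findMirrorMotifs <- function(query, motif = JUNCTION_MOTIF) {
  query <- toupper(as.character(query))
  motif <- toupper(as.character(motif))
  if (nchar(motif) < 5) fail("motif must be at least 5 bases long")
  mirror <- .reverseChars(motif)
  hitsOf <- function(pat, orientation) {
    st <- gregexpr(sprintf("(?=%s)", pat), query, perl = TRUE)[[1]]
    st <- as.integer(st[st > 0])
    if (!length(st)) return(NULL)
    data.frame(motif = pat, start = st, end = st + nchar(pat) - 1L,
               orientation = orientation, stringsAsFactors = FALSE)
  }
  out <- hitsOf(motif, "forward")
  if (mirror != motif) out <- rbind(out, hitsOf(mirror, "mirror"))
  if (is.null(out))
    return(data.frame(motif = character(0), start = integer(0),
                      end = integer(0), orientation = character(0),
                      stringsAsFactors = FALSE))
  out <- out[order(out$start, out$orientation), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Catalog indel and SNP variation in the variable spacer
#'
#' Given a gapped alignment of the variable-spacer segment across
#' haplotypes, counts indel events (a maximal run of gap columns in any row,
#' counted once per distinct gap pattern), gap columns, and SNP sites
#' (gap-free columns with at least two distinct non-missing states), and
#' lists per-haplotype edits relative to a designated reference row.
#'
#' @param vsAlignment Equal-length gapped sequences (>= 2 rows):
#'   [Biostrings::DNAStringSet], named character, or character matrix.
#' @param referenceLabel Reference row (default: first).
#' @return A [VsVariationCatalog-class].
#' @export
catalogVsVariation <- function(vsAlignment, referenceLabel = NULL) {
  m <- asAlignmentMatrix(vsAlignment, "vsAlignment")
  if (nrow(m) < 2) fail("need at least 2 aligned haplotypes")
  if (is.null(rownames(m))) rownames(m) <- paste0("row", seq_len(nrow(m)))
  if (is.null(referenceLabel)) referenceLabel <- rownames(m)[1]
  if (!referenceLabel %in% rownames(m))
    fail("reference label '%s' not among rows", referenceLabel)

  gapRuns <- function(rowName) {
    r <- rle(m[rowName, ] == .GAP_CHAR)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    if (!any(r$values)) return(NULL)
    data.frame(start = starts[r$values], end = ends[r$values])
  }
  allRuns <- do.call(rbind, lapply(rownames(m), gapRuns))
  nEvents <- if (is.null(allRuns)) 0L else nrow(unique(allRuns))
  nGapCols <- sum(colSums(m == .GAP_CHAR) > 0)
  snpCols <- which(vapply(seq_len(ncol(m)), function(j) {
    col <- m[, j]
    !any(col == .GAP_CHAR) &&
      length(unique(col[!col %in% .MISSING_CHARS])) >= 2
  }, logical(1)))

  refRow <- m[referenceLabel, ]
  edits <- lapply(setdiff(rownames(m), referenceLabel), function(h) {
    row <- m[h, ]
    snpAt <- which(row != refRow & row != .GAP_CHAR & refRow != .GAP_CHAR &
                     !row %in% .MISSING_CHARS & !refRow %in% .MISSING_CHARS)
    snps <- data.frame(column = as.integer(snpAt), ref = refRow[snpAt],
                       alt = row[snpAt], stringsAsFactors = FALSE,
                       row.names = NULL)
    dels <- gapRuns(h)
    insRuns <- {
      r <- rle(refRow == .GAP_CHAR & row != .GAP_CHAR)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      if (any(r$values)) data.frame(start = starts[r$values],
                                    end = ends[r$values]) else NULL
    }
    indels <- rbind(
      if (!is.null(dels)) cbind(dels, type = "del"),
      if (!is.null(insRuns)) cbind(insRuns, type = "ins"))
    if (is.null(indels))
      indels <- data.frame(start = integer(0), end = integer(0),
                           type = character(0))
    list(snps = snps, indels = indels)
  })
  names(edits) <- setdiff(rownames(m), referenceLabel)
  methods::new("VsVariationCatalog",
               nIndelEvents = as.integer(nEvents),
               nGapColumns = as.integer(nGapCols),
               nSnpSites = length(snpCols),
               edits = edits, referenceLabel = referenceLabel)
}

#' Length of the COXII-identical prefix of an ORF segment
#'
#' Longest common prefix of the ORF segment and the COXII reference; a
#' missing state (`N`/`?`) in either sequence breaks the match.
#'
#' @param gsv,coxiiRef Sequences (character or [Biostrings::DNAString]).
#' @return Integer prefix length.
#' @export
coxiiPrefixLen <- function(gsv, coxiiRef) {
  a <- strsplit(chartr("?", "N", toupper(as.character(gsv))), "")[[1]]
  b <- strsplit(chartr("?", "N", toupper(as.character(coxiiRef))), "")[[1]]
  if (!length(a) || !length(b)) fail("sequences must be non-empty")
  n <- min(length(a), length(b))
  same <- a[seq_len(n)] == b[seq_len(n)] & a[seq_len(n)] != "N" &
    b[seq_len(n)] != "N"
  if (all(same)) n else which(!same)[1] - 1L
}
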