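#' Collapse sequences into haplotypes
#'
#' Partitions records by exact string equality of the normalized sequence
#' (upper-cased, `?` recoded to `N`; optionally with leading/trailing missing
#' states trimmed). Labels are assigned by descending total count, ties
#' broken lexicographically by representative sequence.
#'
#' @param x A [SurveyBundle-class] (only chimera-assay-positive records are
#'   collapsed), a named [Biostrings::DNAStringSet], or a named character
#'   vector of sequences.
#' @param populations Named character, record id -> population code. Ignored
#'   when `x` is a [SurveyBundle-class] (taken from the bundle). Defaults to
#'   `"NA"` for every record otherwise.
#' @param trimMissingEnds Trim leading/trailing `N`/`?`/`-` before comparing.
#' @param labelPrefix Prefix of the rank labels (`"H"` gives H1, H2, ...;
#'   use `"BH"` for the full-chimera naming style).
#' @return A [HaplotypeSet-class].
#' @export
collapseHaplotypes <- function(x, populations = NULL, trimMissingEnds = FALSE,
                               labelPrefix = "H") {
  if (methods::is(x, "SurveyBundle")) {
    keep <- names(x@sequences)[x@chimeraPositive[names(x@sequences)]]
    populations <- x@population[keep]
    x <- as.character(x@sequences[keep])
  } else if (methods::is(x, "XStringSet")) {
    x <- as.character(x)
  }
  if (!length(x)) fail("no records to collapse")
  if (is.null(names(x)) || any(!nzchar(names(x))))
    fail("records must be named by id")
  if (any(!nzchar(x))) fail("empty sequence among records")
  if (is.null(populations))
    populations <- stats::setNames(rep("NA", length(x)), names(x))
  norm <- chartr("?", "N", toupper(x))
  if (trimMissingEnds)
    norm <- gsub("^[N-]+|[N-]+$", "", norm)
  groups <- split(names(x), factor(norm, levels = unique(norm)))
  sizes <- lengths(groups)
  reps <- names(groups)
  ord <- order(-sizes, reps)
  groups <- groups[ord]; reps <- reps[ord]; sizes <- sizes[ord]
  labels <- paste0(labelPrefix, seq_along(groups))
  popLevels <- unique(populations[names(x)])
  cnt <- vapply(groups, function(ids)
    as.integer(table(factor(populations[ids], levels = popLevels))),
    integer(length(popLevels)))
  counts <- t(matrix(cnt, nrow = length(popLevels), ncol = length(groups)))
  dimnames(counts) <- list(labels, popLevels)
  repSet <- Biostrings::DNAStringSet(reps)
  names(repSet) <- labels
  methods::new("HaplotypeSet", labels = labels, representatives = repSet,
               members = stats::setNames(groups, labels), counts = counts)
}

#' Haplotype assignment of every record
#'
#' @param hset A [HaplotypeSet-class].
#' @return Named character, record id -> haplotype label.
#' @export
haplotypeAssignments <- function(hset) {
  stopifnot(methods::is(hset, "HaplotypeSet"))
  ids <- unlist(hset@members, use.names = FALSE)
  stats::setNames(rep(hset@labels, lengths(hset@members)), ids)
}

#' Per-population haplotype counts
#'
#' @param hset A [HaplotypeSet-class].
#' @return Integer matrix, haplotype x population.
#' @export
haplotypeCounts <- function(hset) {
  stopifnot(methods::is(hset, "HaplotypeSet"))
  hset@counts
}

#' Haplotype labels
#' @param hset A [HaplotypeSet-class].
#' @return Character vector of rank-ordered labels.
#' @export
haplotypeLabels <- function(hset) {
  stopifnot(methods::is(hset, "HaplotypeSet"))
  hset@labels
}

#' Representative sequences
#' @param hset A [HaplotypeSet-class].
#' @return Named [Biostrings::DNAStringSet], one per haplotype.
#' @export
representatives <- function(hset) {
  stopifnot(methods::is(hset, "HaplotypeSet"))
  hset@representatives
}

#' Variable-site matrix in dot notation
#'
#' Finds the alignment columns at which at least two distinct non-missing
#' states occur (missing = `N`/`?`; gaps count as states) and renders them in
#' the dot notation of survey tables: the reference row shows literal states,
#' other rows show `"."` where identical to the reference and `"?"` where the
#' state is unknown.
#'
#' @param aligned Equal-length labeled sequences ([Biostrings::DNAStringSet],
#'   named character, or character matrix).
#' @param referenceLabel Row label used as the reference (default: first).
#' @return A [VariableSiteMatrix-class]; positions are 1-based columns of the
#'   input alignment.
#' @export
variableSites <- function(aligned, referenceLabel = NULL) {
  m <- asAlignmentMatrix(aligned)
  if (is.null(rownames(m))) fail("aligned sequences must be labeled")
  if (is.null(referenceLabel)) referenceLabel <- rownames(m)[1]
  if (!referenceLabel %in% rownames(m))
    fail("reference label '%s' not among sequences", referenceLabel)
  variable <- vapply(seq_len(ncol(m)), function(j) {
    states <- m[, j]
    length(unique(states[!states %in% .MISSING_CHARS])) >= 2
  }, logical(1))
  pos <- which(variable)
  rows <- c(referenceLabel, setdiff(rownames(m), referenceLabel))
  states <- matrix("", nrow = length(rows), ncol = length(pos),
                   dimnames = list(rows, pos))
  for (j in seq_along(pos)) {
    col <- m[rows, pos[j]]
    refState <- col[[referenceLabel]]
    shown <- ifelse(col %in% .MISSING_CHARS, "?", col)
    dotted <- ifelse(!col %in% .MISSING_CHARS &
                       !refState %in% .MISSING_CHARS & col == refState,
                     ".", shown)
    dotted[[referenceLabel]] <- if (refState %in% .MISSING_CHARS) "?" else refState
    states[, j] <- dotted[rows]
  }
  methods::new("VariableSiteMatrix", positions = as.integer(pos),
               referenceLabel = referenceLabel, states = states)
}

#' Percent identity by global alignment
#'
#' Needleman-Wunsch global alignment (no end-gap forgiveness) with linear gap
#' costs, followed by percent identity: identical aligned columns over the
#' denominator. Co-optimal alignments are resolved deterministically by the
#' alignment engine, so the reported identity is reproducible.
#'
#' @param a,b Sequences (character or [Biostrings::DNAString]).
#' @param match,mismatch,gap Scoring (defaults +1 / -1 / -2 per gap column).
#' @param denominator `"alignment"` (full alignment length including gap
#'   columns, the usual global-alignment convention) or `"shorter"` (length
#'   of the shorter input).
#' @return Named numeric of length 2: `identity` (unrounded percent) and
#'   `rounded` (nearest integer percent).
#' @examples
#' identityPercent("ACGT", "ACGA")  # 75
#' @export
identityPercent <- function(a, b, match = 1, mismatch = -1, gap = -2,
                            denominator = c("alignment", "shorter")) {
  denominator <- match.arg(denominator)
  a <- normalizeSequence(as.character(a), "sequence a")
  b <- normalizeSequence(as.character(b), "sequence b")
  if (!nzchar(a) || !nzchar(b)) fail("sequences must be non-empty")
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b), type = "global",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = match, mismatch = mismatch, baseOnly = FALSE),
    gapOpening = 0, gapExtension = abs(gap))
  p <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  nIdent <- sum(p == s & p != "-")
  den <- switch(denominator,
                alignment = length(p),
                shorter = min(nchar(a), nchar(b)))
  pct <- 100 * nIdent / den
  c(identity = pct, rounded = round(pct))
}

#' Pairwise identity matrix
#'
#' @param seqs Named sequences (character or [Biostrings::DNAStringSet]).
#' @param ... Passed to [identityPercent()].
#' @return Symmetric numeric matrix of unrounded percent identities.
#' @export
identityMatrix <- function(seqs, ...) {
  if (methods::is(seqs, "XStringSet")) seqs <- as.character(seqs)
  n <- length(seqs)
  out <- matrix(100, n, n, dimnames = list(names(seqs), names(seqs)))
  if (n > 1) for (i in 1:(n - 1)) for (j in (i + 1):n) {
    out[i, j] <- out[j, i] <- identityPercent(seqs[[i]], seqs[[j]], ...)[["identity"]]
  }
  out
}
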