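#' Translate a nucleotide sequence
#'
#' Translation under the standard genetic code (plant mitochondria use the
#' standard code for these codons). Internal stop codons are rendered `"*"`
#' and translation continues; a trailing partial codon is dropped; any codon
#' containing a missing state (`N`/`?`) or gap translates to `"X"`.
#'
#' @param nt Nucleotide sequence (character or [Biostrings::DNAString]).
#' @param frame Reading frame, 1, 2 or 3.
#' @param code Genetic code: a named character vector codon -> amino acid
#'   (default [Biostrings::GENETIC_CODE], the standard table).
#' @return Single character string of amino acids.
#' @examples
#' translateDNA("ATGGCT")     # "MA"
#' translateDNA("ATGTAAGCT")  # "M*A"
#' @export
translateDNA <- function(nt, frame = 1, code = Biostrings::GENETIC_CODE) {
  if (!frame %in% 1:3) fail("frame must be 1, 2 or 3 (got %s)", frame)
  s <- chartr("?", "N", toupper(as.character(nt)))
  s <- substr(s, frame, nchar(s))
  n <- nchar(s) %/% 3
  if (n == 0) fail("sequence too short to translate in frame %d", frame)
  codons <- substring(s, 3 * seq_len(n) - 2, 3 * seq_len(n))
  aa <- unname(code[codons])
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

#' Group nucleotide haplotypes by their protein product
#'
#' Translates each ORF haplotype in frame 1 and groups the labels by
#' identical amino-acid sequence. Groups are ordered by size (descending),
#' ties by the lexicographically first member label.
#'
#' @param gsvSet Labeled ORF nucleotide haplotypes: named character, named
#'   [Biostrings::DNAStringSet], or a [HaplotypeSet-class] (uses its
#'   representatives).
#' @param ... Passed to [translateDNA()].
#' @return A [ProteinHaplotypeSet-class].
#' @export
proteinHaplotypes <- function(gsvSet, ...) {
  if (methods::is(gsvSet, "HaplotypeSet")) gsvSet <- representatives(gsvSet)
  if (methods::is(gsvSet, "XStringSet")) gsvSet <- as.character(gsvSet)
  if (is.null(names(gsvSet)) || any(!nzchar(names(gsvSet))))
    fail("haplotypes must be labeled")
  aa <- vapply(gsvSet, translateDNA, character(1), ...)
  groups <- split(names(gsvSet), factor(aa, levels = unique(aa)))
  ord <- order(-lengths(groups),
               vapply(groups, function(g) sort(g)[1], character(1)))
  groups <- groups[ord]
  prots <- Biostrings::AAStringSet(names(groups))
  names(prots) <- paste0("P", seq_along(groups))
  methods::new("ProteinHaplotypeSet", proteins = prots,
               members = stats::setNames(unname(groups), names(prots)),
               nDistinct = length(groups))
}
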