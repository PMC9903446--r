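#' Read survey sequences from FASTA
#'
#' Reads a FASTA file of survey amplicons. The population code of each record
#' may be carried in the description line as a `pop=CODE` key; records without
#' one get population `"NA"`. Sequences are upper-cased and validated against
#' the survey alphabet `{A,C,G,T,N,?,-}` (`?` is stored as `N`; both are
#' missing states). Record ids (the first whitespace-delimited token of the
#' header) must be unique.
#'
#' @param path Path to a FASTA file.
#' @return A [SurveyBundle-class] with populations parsed from the headers and
#'   an empty group map.
#' @examples
#' tf <- tempfile(fileext = ".fasta")
#' writeLines(c(">a pop=PS", "ACGT", ">b pop=GZ", "acgt"), tf)
#' bundle <- readFastaRecords(tf)
#' populations(bundle)
#' @export
readFastaRecords <- function(path) {
  if (!file.exists(path)) fail("FASTA file not found: %s", path)
  raw <- Biostrings::readBStringSet(path)
  headers <- names(raw)
  if (is.null(headers) || any(!nzchar(trimws(headers))))
    fail("malformed FASTA: entry with empty header in %s", path)
  ids <- vapply(strsplit(trimws(headers), "\\s+"), `[`, character(1), 1L)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    fail("duplicate sequence id(s) in %s: %s", path, paste(dup, collapse = ", "))
  seqs <- as.character(raw)
  empty <- !nzchar(seqs)
  if (any(empty))
    fail("empty sequence for entry '%s' in %s", ids[which(empty)[1]], path)
  seqs <- vapply(seq_along(seqs), function(i)
    normalizeSequence(seqs[i], context = sprintf("entry '%s'", ids[i])),
    character(1))
  pop <- vapply(headers, function(h) {
    m <- regmatches(h, regexec("\\bpop=([^\\s]+)", h, perl = TRUE))[[1]]
    if (length(m) == 2) m[2] else "NA"
  }, character(1), USE.NAMES = FALSE)
  names(pop) <- ids
  dna <- Biostrings::DNAStringSet(seqs)
  names(dna) <- ids
  methods::new("SurveyBundle",
    sequences = dna, population = pop,
    groupMap = stats::setNames(character(0), character(0)),
    references = Biostrings::DNAStringSet(),
    chimeraPositive = stats::setNames(rep(TRUE, length(ids)), ids))
}

#' Read a two-column mapping from a tab-separated table
#'
#' @param path Path to a tab-separated file with a header row.
#' @param keyCol,valueCol Column names for the keys and values.
#' @return Named character vector mapping keys to values. Duplicate keys with
#'   conflicting values are an error; consistent duplicates are collapsed. An
#'   empty file yields an empty mapping with a warning.
#' @export
readTableMap <- function(path, keyCol, valueCol) {
  if (!file.exists(path)) fail("table file not found: %s", path)
  tab <- tryCatch(
    utils::read.delim(path, header = TRUE, sep = "\t",
                      colClasses = "character", check.names = FALSE),
    error = function(e) NULL)
  if (is.null(tab) || nrow(tab) == 0) {
    warning("empty mapping table: ", path, call. = FALSE)
    return(stats::setNames(character(0), character(0)))
  }
  missingCols <- setdiff(c(keyCol, valueCol), colnames(tab))
  if (length(missingCols))
    fail("column(s) %s absent from %s (found: %s)",
         paste(missingCols, collapse = ", "), path,
         paste(colnames(tab), collapse = ", "))
  keys <- tab[[keyCol]]
  vals <- tab[[valueCol]]
  for (k in unique(keys[duplicated(keys)])) {
    if (length(unique(vals[keys == k])) > 1)
      fail("duplicate key '%s' maps to conflicting values in %s", k, path)
  }
  keep <- !duplicated(keys)
  stats::setNames(vals[keep], keys[keep])
}

#' Assemble a survey bundle from sequences and metadata maps
#'
#' Combines sequence records with a population map and a group map. When a
#' record carries a `pop=` population in its FASTA header *and* appears in the
#' population map, the map wins (survey tables are the primary metadata
#' source).
#'
#' @param bundle A [SurveyBundle-class], e.g. from [readFastaRecords()].
#' @param popMap Optional named character, record id -> population code.
#' @param groupMap Optional named character, population code -> group label.
#' @param references Optional [Biostrings::DNAStringSet] of reference segments
#'   named among `b_atp6`, `ds`, `coxii_prefix`, `gsv_ref`.
#' @return A [SurveyBundle-class].
#' @export
surveyBundle <- function(bundle, popMap = NULL, groupMap = NULL, references = NULL) {
  stopifnot(methods::is(bundle, "SurveyBundle"))
  pop <- bundle@population
  if (!is.null(popMap)) {
    hit <- intersect(names(pop), names(popMap))
    pop[hit] <- popMap[hit]
  }
  methods::new("SurveyBundle",
    sequences = bundle@sequences, population = pop,
    groupMap = if (is.null(groupMap)) bundle@groupMap else groupMap,
    references = if (is.null(references)) bundle@references else references,
    chimeraPositive = bundle@chimeraPositive)
}

#' Write survey records as FASTA
#'
#' Writes the sequences with headers `id pop=CODE`, round-trippable through
#' [readFastaRecords()].
#'
#' @param bundle A [SurveyBundle-class].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
writeFastaRecords <- function(bundle, path) {
  stopifnot(methods::is(bundle, "SurveyBundle"))
  out <- bundle@sequences
  names(out) <- paste0(names(out), " pop=", bundle@population[names(out)])
  Biostrings::writeXStringSet(out, filepath = path)
  invisible(path)
}

.quoteNewickLabel <- function(lab) {
  if (grepl("[][ \t(){}:;,']", lab))
    paste0("'", gsub("'", "''", lab), "'")
  else lab
}

#' Write a tree in Newick format
#'
#' Branch lengths are written with 6 decimal places; labels containing
#' whitespace or Newick metacharacters are single-quoted (embedded quotes
#' doubled). The output re-parses with [ape::read.tree()] to the same
#' topology with branch lengths equal to 1e-6.
#'
#' @param tree A `phylo` object or a [PhyloFit-class].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
writeNewick <- function(tree, path) {
  if (methods::is(tree, "PhyloFit")) tree <- tree@tree
  stopifnot(inherits(tree, "phylo"))
  nTip <- length(tree$tip.label)
  if (nTip < 2) fail("tree must have at least 2 leaves")
  if (any(is.na(tree$tip.label)) || any(!nzchar(tree$tip.label)))
    fail("tree has an unnamed leaf")
  edge <- tree$edge
  el <- tree$edge.length
  if (is.null(el)) el <- rep(0, nrow(edge))
  kids <- split(seq_len(nrow(edge)), edge[, 1])
  rec <- function(node) {
    if (node <= nTip) return(.quoteNewickLabel(tree$tip.label[node]))
    rows <- kids[[as.character(node)]]
    paste0("(", paste(vapply(rows, function(r) {
      paste0(rec(edge[r, 2]), ":", sprintf("%.6f", el[r]))
    }, character(1)), collapse = ","), ")")
  }
  root <- nTip + 1L
  writeLines(paste0(rec(root), ";"), path)
  invisible(path)
}
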