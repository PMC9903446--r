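# Accessors for the survey containers (slot access stays internal).

#' Accessors for SurveyBundle
#'
#' @param x A [SurveyBundle-class].
#' @return `recordSequences`: the named [Biostrings::DNAStringSet];
#'   `populations`: named character, record id -> population code;
#'   `groupMap`: named character, population -> group; `chimeraPositive`:
#'   named logical, whether the chimera assay amplified.
#' @name SurveyBundle-accessors
NULL

#' @rdname SurveyBundle-accessors
#' @export
recordSequences <- function(x) {
  stopifnot(methods::is(x, "SurveyBundle"))
  x@sequences
}

#' @rdname SurveyBundle-accessors
#' @export
populations <- function(x) {
  stopifnot(methods::is(x, "SurveyBundle"))
  x@population
}

#' @rdname SurveyBundle-accessors
#' @export
groupMap <- function(x) {
  stopifnot(methods::is(x, "SurveyBundle"))
  x@groupMap
}

#' @rdname SurveyBundle-accessors
#' @export
chimeraPositive <- function(x) {
  stopifnot(methods::is(x, "SurveyBundle"))
  x@chimeraPositive
}

#' Accessors for StructureAnnotation
#'
#' @param x A [StructureAnnotation-class].
#' @return `segmentRanges`: named [IRanges::IRanges] of located segments;
#'   `missingSegments`: character; `motifHits`: data.frame of junction-motif
#'   hits.
#' @name StructureAnnotation-accessors
NULL

#' @rdname StructureAnnotation-accessors
#' @export
segmentRanges <- function(x) {
  stopifnot(methods::is(x, "StructureAnnotation"))
  x@segments
}

#' @rdname StructureAnnotation-accessors
#' @export
missingSegments <- function(x) {
  stopifnot(methods::is(x, "StructureAnnotation"))
  x@missingSegments
}

#' @rdname StructureAnnotation-accessors
#' @export
motifHits <- function(x) {
  stopifnot(methods::is(x, "StructureAnnotation"))
  x@motifHits
}

#' Accessors for AmovaResult
#'
#' @param x An [AmovaResult-class].
#' @return `phiStatistics`: named numeric (phiCT, phiSC, phiST);
#'   `varianceComponents`: named numeric (Va, Vb, Vc); `amovaPValues`:
#'   named numeric of permutation p-values; `sumsOfSquares` and
#'   `degreesOfFreedom`: named numeric per stratum plus total;
#'   `variancePercentages`: percent of total variance per component.
#' @name AmovaResult-accessors
NULL

#' @rdname AmovaResult-accessors
#' @export
phiStatistics <- function(x) {
  stopifnot(methods::is(x, "AmovaResult"))
  x@phi
}

#' @rdname AmovaResult-accessors
#' @export
varianceComponents <- function(x) {
  stopifnot(methods::is(x, "AmovaResult"))
  x@varianceComponents
}

#' @rdname AmovaResult-accessors
#' @export
amovaPValues <- function(x) {
  stopifnot(methods::is(x, "AmovaResult"))
  x@pValues
}

#' @rdname AmovaResult-accessors
#' @export
sumsOfSquares <- function(x) {
  stopifnot(methods::is(x, "AmovaResult"))
  x@ss
}

#' @rdname AmovaResult-accessors
#' @export
degreesOfFreedom <- function(x) {
  stopifnot(methods::is(x, "AmovaResult"))
  x@df
}

#' @rdname AmovaResult-accessors
#' @export
variancePercentages <- function(x) {
  stopifnot(methods::is(x, "AmovaResult"))
  x@percentages
}

#' Accessors for PhyloFit
#'
#' @param x A [PhyloFit-class].
#' @return `fittedTree`: the `phylo` tree; `treeLogLik`: numeric
#'   log-likelihood; `treeModel`: the [PhyloModel-class]; `edgeSupports`:
#'   bootstrap support fractions (length 0 when not computed).
#' @name PhyloFit-accessors
NULL

#' @rdname PhyloFit-accessors
#' @export
fittedTree <- function(x) {
  stopifnot(methods::is(x, "PhyloFit"))
  x@tree
}

#' @rdname PhyloFit-accessors
#' @export
treeLogLik <- function(x) {
  stopifnot(methods::is(x, "PhyloFit"))
  x@logLik
}

#' @rdname PhyloFit-accessors
#' @export
treeModel <- function(x) {
  stopifnot(methods::is(x, "PhyloFit"))
  x@model
}

#' @rdname PhyloFit-accessors
#' @export
edgeSupports <- function(x) {
  stopifnot(methods::is(x, "PhyloFit"))
  x@supports
}

#' Accessors for VsVariationCatalog
#'
#' @param x A [VsVariationCatalog-class].
#' @return `indelEvents`/`snpSites`/`gapColumns`: integer counts;
#'   `vsEdits`: per-haplotype edit lists relative to the reference row.
#' @name VsVariationCatalog-accessors
NULL

#' @rdname VsVariationCatalog-accessors
#' @export
indelEvents <- function(x) {
  stopifnot(methods::is(x, "VsVariationCatalog"))
  x@nIndelEvents
}

#' @rdname VsVariationCatalog-accessors
#' @export
snpSites <- function(x) {
  stopifnot(methods::is(x, "VsVariationCatalog"))
  x@nSnpSites
}

#' @rdname VsVariationCatalog-accessors
#' @export
gapColumns <- function(x) {
  stopifnot(methods::is(x, "VsVariationCatalog"))
  x@nGapColumns
}

#' @rdname VsVariationCatalog-accessors
#' @export
vsEdits <- function(x) {
  stopifnot(methods::is(x, "VsVariationCatalog"))
  x@edits
}

#' Variable-site matrix in printable dot notation
#'
#' @param x A [VariableSiteMatrix-class].
#' @return Character matrix (haplotype x position) with the reference row
#'   first; column names are the 1-based positions.
#' @export
siteMatrix <- function(x) {
  stopifnot(methods::is(x, "VariableSiteMatrix"))
  x@states
}

#' Variable site positions
#' @param x A [VariableSiteMatrix-class].
#' @return Integer vector of 1-based positions.
#' @export
sitePositions <- function(x) {
  stopifnot(methods::is(x, "VariableSiteMatrix"))
  x@positions
}

#' Protein haplotype count
#' @param x A [ProteinHaplotypeSet-class].
#' @return Integer: number of distinct protein haplotypes.
#' @export
nProteinHaplotypes <- function(x) {
  stopifnot(methods::is(x, "ProteinHaplotypeSet"))
  x@nDistinct
}

#' Deduced protein sequences
#' @param x A [ProteinHaplotypeSet-class].
#' @return Named [Biostrings::AAStringSet].
#' @export
proteinSequences <- function(x) {
  stopifnot(methods::is(x, "ProteinHaplotypeSet"))
  x@proteins
}

#' Members of each protein haplotype
#' @param x A [ProteinHaplotypeSet-class].
#' @return Named list of nucleotide-haplotype labels.
#' @export
proteinMembers <- function(x) {
  stopifnot(methods::is(x, "ProteinHaplotypeSet"))
  x@members
}
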