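#' @import methods
#' @importFrom Biostrings DNAStringSet AAStringSet
NULL

setOldClass("phylo")

#' SurveyBundle: sequences plus survey metadata
#'
#' Container for one survey dataset: the sequenced amplicons, the population
#' each individual belongs to, the population-to-group map used by the
#' hierarchical AMOVA, and optional reference segments of the chimeric locus
#' (`b_atp6`, `ds`, `coxii_prefix`, `gsv_ref`).
#'
#' @slot sequences [Biostrings::DNAStringSet] named by record id.
#' @slot population named character; population code per record id.
#' @slot groupMap named character; group label per population code.
#' @slot references [Biostrings::DNAStringSet] of reference segments (possibly
#'   empty); names drawn from `b_atp6`, `ds`, `coxii_prefix`, `gsv_ref`.
#' @slot chimeraPositive named logical; whether the chimera assay amplified
#'   for the record (absence of the locus is data, not an error).
#' @exportClass SurveyBundle
setClass("SurveyBundle",
  representation(
    sequences = "DNAStringSet",
    population = "character",
    groupMap = "character",
    references = "DNAStringSet",
    chimeraPositive = "logical"
  )
)

.refVocabulary <- c("b_atp6", "ds", "coxii_prefix", "gsv_ref", "vs", "gsv")

setValidity("SurveyBundle", function(object) {
  ids <- names(object@sequences)
  if (is.null(ids) || any(!nzchar(ids))) return("all sequences must have non-empty ids")
  if (anyDuplicated(ids)) {
    return(paste0("duplicate record id(s): ",
                  paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  if (length(object@sequences) && any(Biostrings::width(object@sequences) == 0))
    return("zero-length sequence present")
  if (!identical(sort(names(object@population)), sort(ids)))
    return("population must be named by exactly the record ids")
  if (length(object@references) &&
      !all(names(object@references) %in% .refVocabulary))
    return(paste0("reference names must be in: ",
                  paste(.refVocabulary, collapse = ", ")))
  if (length(object@chimeraPositive) &&
      !identical(sort(names(object@chimeraPositive)), sort(ids)))
    return("chimeraPositive must be named by exactly the record ids")
  TRUE
})

#' HaplotypeSet: collapsed haplotypes with per-population counts
#'
#' @slot labels character; rank-ordered haplotype labels (e.g. "H1", "H2").
#' @slot representatives [Biostrings::DNAStringSet], one per haplotype.
#' @slot members list of character vectors; record ids per haplotype.
#' @slot counts integer matrix, haplotype x population.
#' @exportClass HaplotypeSet
setClass("HaplotypeSet",
  representation(
    labels = "character",
    representatives = "DNAStringSet",
    members = "list",
    counts = "matrix"
  )
)

setValidity("HaplotypeSet", function(object) {
  k <- length(object@labels)
  if (anyDuplicated(object@labels)) return("haplotype labels must be unique")
  if (length(object@representatives) != k || length(object@members) != k)
    return("labels, representatives and members must be parallel")
  if (nrow(object@counts) != k) return("counts must have one row per haplotype")
  if (sum(object@counts) != length(unlist(object@members)))
    return("counts must sum to the number of member records")
  TRUE
})

#' VariableSiteMatrix: dot-notation variable sites
#'
#' Columns are the 1-based positions (on the input alignment) at which at
#' least two distinct non-missing states occur. The reference row shows its
#' literal states; other rows show "." where identical to the reference and
#' "?" where the state is missing/unknown.
#'
#' @slot positions integer; 1-based variable site positions.
#' @slot referenceLabel character scalar.
#' @slot states character matrix, haplotype x position, in dot notation.
#' @exportClass VariableSiteMatrix
setClass("VariableSiteMatrix",
  representation(
    positions = "integer",
    referenceLabel = "character",
    states = "matrix"
  )
)

setValidity("VariableSiteMatrix", function(object) {
  if (ncol(object@states) != length(object@positions))
    return("states must have one column per position")
  if (!object@referenceLabel %in% rownames(object@states))
    return("reference row absent from states")
  TRUE
})

#' StructureAnnotation: chimeric architecture of one query sequence
#'
#' @slot segments [IRanges::IRanges], named among `b_atp6`, `ds`, `vs`, `gsv`;
#'   1-based inclusive coordinates on the query. Missing segments are listed
#'   in `missingSegments`, not as ranges.
#' @slot missingSegments character; segments not located above threshold.
#' @slot motifHits data.frame with columns motif, start, end, orientation.
#' @slot coxiiPrefixLen integer; length of the COXII-identical prefix of the
#'   ORF segment (NA when not assessed).
#' @slot notes character; free-text remarks (unannotated flanks etc.).
#' @exportClass StructureAnnotation
setClass("StructureAnnotation",
  representation(
    segments = "IRanges",
    missingSegments = "character",
    motifHits = "data.frame",
    coxiiPrefixLen = "integer",
    notes = "character"
  )
)

setValidity("StructureAnnotation", function(object) {
  segs <- object@segments
  nm <- names(segs)
  if (length(segs)) {
    if (is.null(nm) || !all(nm %in% c("b_atp6", "ds", "vs", "gsv")))
      return("segment names must be among b_atp6, ds, vs, gsv")
    ord <- match(c("b_atp6", "ds", "vs", "gsv"), nm)
    ord <- ord[!is.na(ord)]
    st <- IRanges::start(segs)[ord]
    en <- IRanges::end(segs)[ord]
    if (length(ord) > 1 && any(diff(st) <= 0))
      return("segments must be ordered b_atp6 < ds < vs < gsv")
    if (length(ord) > 1 && any(st[-1] <= en[-length(en)]))
      return("segments must not overlap")
  }
  TRUE
})

#' VsVariationCatalog: indel/SNP catalog of the variable spacer
#'
#' @slot nIndelEvents integer; distinct maximal gap runs across rows.
#' @slot nGapColumns integer; alignment columns containing any gap.
#' @slot nSnpSites integer; gap-free columns with >= 2 distinct non-missing states.
#' @slot edits list; per-haplotype edits relative to the reference row, each a
#'   list with data.frames `snps` (column, ref, alt) and `indels`
#'   (start, end, type).
#' @slot referenceLabel character scalar.
#' @exportClass VsVariationCatalog
setClass("VsVariationCatalog",
  representation(
    nIndelEvents = "integer",
    nGapColumns = "integer",
    nSnpSites = "integer",
    edits = "list",
    referenceLabel = "character"
  )
)

#' ProteinHaplotypeSet: nucleotide haplotypes grouped by translation
#'
#' @slot proteins [Biostrings::AAStringSet]; one deduced amino-acid sequence
#'   per protein haplotype, ordered by group size then label.
#' @slot members list of character vectors; nucleotide-haplotype labels per
#'   protein haplotype.
#' @slot nDistinct integer; number of distinct protein haplotypes.
#' @exportClass ProteinHaplotypeSet
setClass("ProteinHaplotypeSet",
  representation(
    proteins = "AAStringSet",
    members = "list",
    nDistinct = "integer"
  )
)

setValidity("ProteinHaplotypeSet", function(object) {
  if (length(object@proteins) != length(object@members))
    return("proteins and members must be parallel")
  if (object@nDistinct != length(object@proteins))
    return("nDistinct must equal the number of protein groups")
  TRUE
})

#' AmovaResult: hierarchical analysis of molecular variance
#'
#' Two-level (groups / populations within groups / within populations) or
#' one-level partition of squared pairwise distances, with Phi fixation
#' indices and permutation p-values.
#'
#' @slot df named numeric; degrees of freedom per stratum plus total.
#' @slot ss named numeric; sums of squares per stratum plus total.
#' @slot varianceComponents named numeric (Va, Vb, Vc).
#' @slot percentages named numeric; percent of total variance per component.
#' @slot phi named numeric (phiCT, phiSC, phiST); NA where undefined.
#' @slot pValues named numeric; permutation p-values per Phi statistic.
#' @slot nPermutations integer.
#' @slot seed integer (NA when unseeded).
#' @exportClass AmovaResult
setClass("AmovaResult",
  representation(
    df = "numeric",
    ss = "numeric",
    varianceComponents = "numeric",
    percentages = "numeric",
    phi = "numeric",
    pValues = "numeric",
    nPermutations = "integer",
    seed = "integer"
  )
)

setValidity("AmovaResult", function(object) {
  strata <- setdiff(names(object@df), "total")
  if (abs(sum(object@df[strata]) - object@df[["total"]]) > 1e-9)
    return("degrees of freedom must sum to the total")
  if (abs(sum(object@ss[strata]) - object@ss[["total"]]) > 1e-9)
    return("sums of squares must sum to the total")
  TRUE
})

#' PhyloModel: HKY85 substitution model parameters
#'
#' @slot kappa numeric; transition/transversion rate ratio (> 0).
#' @slot freqs numeric length 4; base frequencies (A, C, G, T) summing to 1.
#' @exportClass PhyloModel
setClass("PhyloModel",
  representation(kappa = "numeric", freqs = "numeric")
)

setValidity("PhyloModel", function(object) {
  if (length(object@kappa) != 1 || object@kappa <= 0) return("kappa must be a positive scalar")
  f <- object@freqs
  if (length(f) != 4 || any(f <= 0)) return("freqs must be 4 positive values")
  if (abs(sum(f) - 1) > 1e-9) return("freqs must sum to 1")
  TRUE
})

#' PhyloFit: a fitted maximum-likelihood tree
#'
#' @slot tree an [ape::read.tree()]-style `phylo` object with branch lengths
#'   in expected substitutions per site.
#' @slot logLik numeric; log-likelihood under the HKY85 model.
#' @slot model [PhyloModel-class].
#' @slot supports numeric; optional bootstrap support fractions per internal
#'   node (ape node order), length 0 when not computed.
#' @exportClass PhyloFit
setClass("PhyloFit",
  representation(
    tree = "phylo",
    logLik = "numeric",
    model = "PhyloModel",
    supports = "numeric"
  )
)

#' RunReport: outputs of one pipeline run
#'
#' @slot stages named list; one output block per enabled stage.
#' @slot warnings character; stage failures and notes (stage failures are
#'   isolated: later independent stages still run).
#' @slot provenance list; seed, config echo, package and R versions.
#' @exportClass RunReport
setClass("RunReport",
  representation(stages = "list", warnings = "character", provenance = "list")
)
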