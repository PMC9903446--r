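setMethod("show", "SurveyBundle", function(object) {
  pos <- sum(object@chimeraPositive)
  cat(sprintf("SurveyBundle: %d records, %d populations (%d chimera-positive)\n",
              length(object@sequences), length(unique(object@population)), pos))
  if (length(object@groupMap))
    cat("  groups:", paste(sprintf("%s=%s", names(object@groupMap),
                                   object@groupMap), collapse = ", "), "\n")
  if (length(object@references))
    cat("  references:", paste(names(object@references), collapse = ", "), "\n")
})

setMethod("show", "HaplotypeSet", function(object) {
  cat(sprintf("HaplotypeSet: %d haplotypes over %d records\n",
              length(object@labels), sum(object@counts)))
  print(object@counts)
})

setMethod("show", "VariableSiteMatrix", function(object) {
  cat(sprintf("VariableSiteMatrix: %d variable sites (reference %s)\n",
              length(object@positions), object@referenceLabel))
  print(object@states, quote = FALSE)
})

setMethod("show", "StructureAnnotation", function(object) {
  cat("StructureAnnotation\n")
  if (length(object@segments)) {
    segs <- object@segments
    for (nm in names(segs))
      cat(sprintf("  %-7s %d-%d (%d bp)\n", nm,
                  IRanges::start(segs[nm]), IRanges::end(segs[nm]),
                  IRanges::width(segs[nm])))
  }
  if (length(object@missingSegments))
    cat("  missing:", paste(object@missingSegments, collapse = ", "), "\n")
  if (nrow(object@motifHits))
    cat(sprintf("  %d junction-motif hit(s)\n", nrow(object@motifHits)))
  if (!is.na(object@coxiiPrefixLen))
    cat("  COXII prefix length:", object@coxiiPrefixLen, "\n")
  for (n in object@notes) cat("  note:", n, "\n")
})

setMethod("show", "VsVariationCatalog", function(object) {
  cat(sprintf(paste0("VsVariationCatalog: %d indel events, %d gap columns, ",
                     "%d SNP sites (reference %s)\n"),
              object@nIndelEvents, object@nGapColumns, object@nSnpSites,
              object@referenceLabel))
})

setMethod("show", "ProteinHaplotypeSet", function(object) {
  cat(sprintf("ProteinHaplotypeSet: %d protein haplotypes\n", object@nDistinct))
  for (i in seq_along(object@members))
    cat(sprintf("  %s: %s\n", names(object@members)[i],
                paste(object@members[[i]], collapse = ", ")))
})

setMethod("show", "AmovaResult", function(object) {
  cat("AMOVA\n")
  print(amovaTable(object), row.names = FALSE, digits = 6)
  cat(sprintf("  (%d permutations)\n", object@nPermutations))
})

setMethod("show", "PhyloModel", function(object) {
  cat(sprintf("HKY85 model: kappa = %.4f, freqs (A,C,G,T) = %s\n",
              object@kappa, paste(sprintf("%.4f", object@freqs),
                                  collapse = ", ")))
})

setMethod("show", "PhyloFit", function(object) {
  cat(sprintf("PhyloFit: %d tips, logLik = %.4f\n",
              length(object@tree$tip.label), object@logLik))
  show(object@model)
  if (length(object@supports))
    cat("  bootstrap supports on", length(object@supports), "nodes\n")
})

setMethod("show", "RunReport", function(object) {
  cat("RunReport: stages", paste(names(object@stages), collapse = ", "), "\n")
  if (length(object@warnings))
    for (w in object@warnings) cat("  warning:", w, "\n")
})

setMethod("show", "ReferenceChimera", function(object) {
  cat(sprintf("ReferenceChimera: b_atp6 %d bp, ds %d bp, vs %d bp, gsv %d bp\n",
              nchar(object@bAtp6), nchar(object@ds), nchar(object@vs),
              nchar(object@gsv)))
})

setMethod("show", "SurveyDesign", function(object) {
  p <- object@populations
  cat(sprintf("SurveyDesign: %d populations, %d carriers, %d sequenced\n",
              nrow(p), sum(!is.na(p$haplotype)), sum(p$nSequenced)))
})
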