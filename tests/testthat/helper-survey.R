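# One shared simulation of the emulated survey design; built once per test run.
.surveyCache <- new.env(parent = emptyenv())

paperSim <- function(seed = 1L) {
  key <- paste0("s", seed)
  if (is.null(.surveyCache[[key]]))
    .surveyCache[[key]] <- simulateSurvey(paperSurveyDesign(seed))
  .surveyCache[[key]]
}

# The five carrier populations and their expected haplotype layout
CARRIER_COUNTS <- c(PS = 15L, GZ = 15L, TL = 15L, HK = 15L, YJ = 5L)
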