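.KNOWN_STAGES <- c("simulate", "haplotypes", "structure", "orfs", "amova", "phylo")

.defaultConfig <- function() {
  list(
    seed = 1L,
    stages = .KNOWN_STAGES,
    simulate = list(design = "paper", gsv_length = 214L),
    input = NULL,
    haplotypes = list(trim_missing_ends = FALSE, label_prefix = "H"),
    amova = list(n_perm = 1000L, distance = "haplotype_binary"),
    phylo = list(bootstrap = 0L)
  )
}

.validateConfig <- function(config) {
  known <- names(.defaultConfig())
  bad <- setdiff(names(config), known)
  if (length(bad))
    fail("invalid config key(s): %s (known: %s)",
         paste(bad, collapse = ", "), paste(known, collapse = ", "))
  merged <- .defaultConfig()
  for (k in names(config)) {
    if (is.list(config[[k]]) && is.list(merged[[k]]))
      merged[[k]] <- utils::modifyList(merged[[k]], config[[k]])
    else merged[[k]] <- config[[k]]
  }
  badStage <- setdiff(merged$stages, .KNOWN_STAGES)
  if (length(badStage))
    fail("invalid stage(s): %s (known: %s)",
         paste(badStage, collapse = ", "), paste(.KNOWN_STAGES, collapse = ", "))
  merged
}

#' Run the survey pipeline end to end
#'
#' Executes the enabled stages in order: simulate (or load input files),
#' collapse into haplotypes (with variable sites and pairwise identity),
#' structure annotation and variable-spacer catalog, protein haplotypes,
#' hierarchical AMOVA, and the maximum-likelihood tree of the ORF
#' haplotypes. A stage failure is recorded in the report's warnings and
#' later independent stages still run. With identical config (including
#' seed) two runs produce identical reports.
#'
#' @param config A nested list, or the path of a YAML file holding one.
#'   Recognized keys: `seed`; `stages` (subset of `simulate`, `haplotypes`,
#'   `structure`, `orfs`, `amova`, `phylo`); `simulate` (`design = "paper"`,
#'   `gsv_length`); `input` (`fasta`, `pop_map`, `group_map` file paths, as
#'   an alternative to `simulate`); `haplotypes` (`trim_missing_ends`,
#'   `label_prefix`); `amova` (`n_perm`, `distance`); `phylo` (`bootstrap`
#'   replicate count).
#' @param outDir Optional directory for file outputs (haplotype table,
#'   variable-site matrix, identity matrix, AMOVA table, Newick tree,
#'   JSON report).
#' @return A [RunReport-class].
#' @export
runPipeline <- function(config = list(), outDir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- .validateConfig(config)
  stages <- cfg$stages
  report <- list()
  warnings <- character(0)
  note <- function(msg) warnings <<- c(warnings, msg)
  if (!length(stages)) {
    warning("no stages enabled; empty report", call. = FALSE)
    return(methods::new("RunReport", stages = list(),
                        warnings = "no stages enabled",
                        provenance = .provenance(cfg)))
  }
  bundle <- NULL
  truth <- NULL
  tryStage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      note(sprintf("stage '%s' failed: %s", name, conditionMessage(e)))
      NULL
    })
  }

  if ("simulate" %in% stages) {
    sim <- tryStage("simulate", {
      if (!identical(cfg$simulate$design, "paper"))
        fail("only the 'paper' design is built in; pass a SurveyDesign to simulateSurvey() directly for custom designs")
      design <- paperSurveyDesign(seed = cfg$seed)
      ref <- makeReferenceChimera(cfg$seed, gsvLength = cfg$simulate$gsv_length)
      simulateSurvey(design, ref)
    })
    if (!is.null(sim)) {
      bundle <- sim$bundle
      truth <- sim$truth
      report$simulate <- list(
        nRecords = length(recordSequences(bundle)),
        nChimeraPositive = sum(chimeraPositive(bundle)),
        nHaplotypesTrue = truth$nHaplotypes)
    }
  } else if (!is.null(cfg$input)) {
    bundle <- tryStage("input", {
      b <- readFastaRecords(cfg$input$fasta)
      popMap <- if (!is.null(cfg$input$pop_map))
        readTableMap(cfg$input$pop_map, "id", "population") else NULL
      grpMap <- if (!is.null(cfg$input$group_map))
        readTableMap(cfg$input$group_map, "population", "group") else NULL
      surveyBundle(b, popMap = popMap, groupMap = grpMap)
    })
  }
  if (is.null(bundle) && length(setdiff(stages, "simulate"))) {
    note("no input available; downstream stages skipped")
    return(methods::new("RunReport", stages = report, warnings = warnings,
                        provenance = .provenance(cfg)))
  }

  hset <- NULL
  gsvSet <- NULL
  if ("haplotypes" %in% stages && !is.null(bundle)) {
    hset <- tryStage("haplotypes", collapseHaplotypes(
      bundle, trimMissingEnds = isTRUE(cfg$haplotypes$trim_missing_ends),
      labelPrefix = cfg$haplotypes$label_prefix))
    if (!is.null(hset)) {
      idm <- tryStage("haplotypes",
                      identityMatrix(representatives(hset)))
      report$haplotypes <- list(set = hset, counts = haplotypeCounts(hset),
                                identity = idm)
    }
  }

  annotations <- NULL
  if ("structure" %in% stages && !is.null(hset)) {
    res <- tryStage("structure", {
      refs <- bundle@references
      if (!length(refs)) fail("no reference segments available")
      anns <- lapply(as.character(representatives(hset)), annotateStructure,
                     refs = refs)
      names(anns) <- haplotypeLabels(hset)
      gsv <- vapply(names(anns), function(h) {
        segs <- segmentRanges(anns[[h]])
        if (!"gsv" %in% names(segs)) return(NA_character_)
        substr(as.character(representatives(hset)[[h]]),
               IRanges::start(segs["gsv"]), IRanges::end(segs["gsv"]))
      }, character(1))
      cat_ <- if (!is.null(truth))
        catalogVsVariation(truth$vsAlignment,
                           referenceLabel = rownames(truth$vsAlignment)[1])
      else NULL
      list(annotations = anns, gsv = gsv, vsCatalog = cat_)
    })
    if (!is.null(res)) {
      annotations <- res$annotations
      gsvSet <- res$gsv[!is.na(res$gsv)]
      report$structure <- res
    }
  }

  if (!is.null(gsvSet) && length(gsvSet) >= 2 &&
      length(unique(nchar(gsvSet))) == 1) {
    vsm <- tryStage("haplotypes", variableSites(gsvSet))
    if (!is.null(vsm) && !is.null(report$haplotypes))
      report$haplotypes$variableSites <- vsm
  }

  if ("orfs" %in% stages && !is.null(gsvSet)) {
    prot <- tryStage("orfs", proteinHaplotypes(gsvSet))
    if (!is.null(prot))
      report$orfs <- list(proteins = prot,
                          nDistinct = nProteinHaplotypes(prot))
  }

  if ("amova" %in% stages && !is.null(hset)) {
    am <- tryStage("amova", {
      grp <- groupMap(bundle)
      if (!length(grp)) fail("group map required for the AMOVA stage")
      assign_ <- haplotypeAssignments(hset)
      d2 <- if (identical(cfg$amova$distance, "nt_differences")) {
        ids <- names(assign_)
        seqs <- stats::setNames(
          as.character(recordSequences(bundle)[ids]), ids)
        distanceMatrix(seqs, mode = "nt_differences")
      } else {
        distanceMatrix(assign_, mode = "haplotype_binary")
      }
      pops <- populations(bundle)[rownames(d2)]
      amova(d2, pops, groups = grp, nPerm = cfg$amova$n_perm,
            seed = cfg$seed)
    })
    if (!is.null(am))
      report$amova <- list(result = am, table = amovaTable(am))
  }

  if ("phylo" %in% stages && !is.null(gsvSet)) {
    ph <- tryStage("phylo", {
      if (length(gsvSet) < 3)
        fail("phylogeny needs at least 3 haplotypes")
      if (length(unique(nchar(gsvSet))) != 1)
        fail("ORF haplotypes differ in length; align them before the phylo stage")
      fit <- mlSearch(gsvSet)
      nb <- cfg$phylo$bootstrap
      if (!is.null(nb) && nb > 0)
        fit <- bootstrapSupports(gsvSet, nReps = nb, seed = cfg$seed,
                                 tree = fit)
      fit
    })
    if (!is.null(ph)) report$phylo <- list(fit = ph)
  }

  out <- methods::new("RunReport", stages = report, warnings = warnings,
                      provenance = .provenance(cfg))
  if (!is.null(outDir)) writeRunReport(out, outDir)
  out
}

.provenance <- function(cfg) {
  list(seed = cfg$seed, config = cfg,
       package = as.character(utils::packageVersion("chimeraCMS")),
       r_version = R.version.string)
}

#' Write pipeline outputs to a directory
#'
#' Fixed file names: `haplotypes.tsv` (counts per population),
#' `identity.tsv`, `variable_sites.tsv` (dot notation), `amova.tsv`,
#' `tree.nwk`, and `report.json` (scalar summaries and provenance).
#'
#' @param report A [RunReport-class].
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
writeRunReport <- function(report, dir) {
  stopifnot(methods::is(report, "RunReport"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  st <- report@stages
  writeTsv <- function(x, f)
    utils::write.table(x, file.path(dir, f), sep = "\t", quote = FALSE,
                       col.names = NA)
  if (!is.null(st$haplotypes)) {
    writeTsv(st$haplotypes$counts, "haplotypes.tsv")
    if (!is.null(st$haplotypes$identity))
      writeTsv(round(st$haplotypes$identity, 2), "identity.tsv")
    if (!is.null(st$haplotypes$variableSites))
      writeTsv(siteMatrix(st$haplotypes$variableSites), "variable_sites.tsv")
  }
  if (!is.null(st$amova))
    utils::write.table(st$amova$table, file.path(dir, "amova.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(st$phylo))
    writeNewick(st$phylo$fit, file.path(dir, "tree.nwk"))
  summary_ <- list(
    provenance = report@provenance,
    warnings = report@warnings,
    stages = lapply(st, function(block) {
      block[vapply(block, function(el)
        is.atomic(el) && length(el) <= 16, logical(1))]
    }))
  jsonlite::write_json(summary_, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(dir)
}

#' Write a simulated survey as portable files
#'
#' Writes the FASTA of all records (with `pop=` header keys), the
#' id-to-population and population-to-group tables, the reference segments,
#' and the ground truth as JSON.
#'
#' @param sim Result of [simulateSurvey()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
writeSurveyData <- function(sim, dir) {
  stopifnot(is.list(sim), !is.null(sim$bundle))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  bundle <- sim$bundle
  writeFastaRecords(bundle, file.path(dir, "survey.fasta"))
  utils::write.table(
    data.frame(id = names(populations(bundle)),
               population = unname(populations(bundle))),
    file.path(dir, "populations.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  utils::write.table(
    data.frame(population = names(groupMap(bundle)),
               group = unname(groupMap(bundle))),
    file.path(dir, "groups.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  Biostrings::writeXStringSet(bundle@references,
                              file.path(dir, "references.fasta"))
  truth <- sim$truth
  truth$reference <- NULL
  truth$vsAlignment <- apply(sim$truth$vsAlignment, 1, paste, collapse = "")
  truth$countsByPopulation <- as.data.frame(sim$truth$countsByPopulation)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(dir)
}
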