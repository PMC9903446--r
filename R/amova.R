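#' Squared-distance matrix between survey records
#'
#' Two conventions: `"haplotype_binary"` assigns squared distance 0 between
#' records of the same haplotype and 1 otherwise (the convention that
#' reproduces whole-haplotype survey AMOVA tables exactly);
#' `"nt_differences"` uses the squared number of differing aligned positions,
#' with missing states ignored.
#'
#' @param x For `"haplotype_binary"`: a named character of haplotype labels
#'   per record id (e.g. [haplotypeAssignments()]) or a
#'   [HaplotypeSet-class]. For `"nt_differences"`: equal-length aligned
#'   sequences (named character, [Biostrings::DNAStringSet], or character
#'   matrix).
#' @param mode Distance convention.
#' @return Symmetric numeric matrix of squared distances with zero diagonal,
#'   labeled by record id.
#' @export
distanceMatrix <- function(x, mode = c("haplotype_binary", "nt_differences")) {
  mode <- match.arg(mode)
  if (mode == "haplotype_binary") {
    if (methods::is(x, "HaplotypeSet")) x <- haplotypeAssignments(x)
    if (is.null(names(x))) fail("haplotype assignments must be named by record id")
    d2 <- outer(x, x, FUN = `!=`) * 1
  } else {
    m <- asAlignmentMatrix(x, "sequences")
    if (is.null(rownames(m))) fail("sequences must be named by record id")
    n <- nrow(m)
    miss <- isMissingState(m)
    d2 <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
    if (n > 1) for (i in 1:(n - 1)) for (j in (i + 1):n) {
      ok <- !miss[i, ] & !miss[j, ]
      nd <- sum(m[i, ok] != m[j, ok])
      d2[i, j] <- d2[j, i] <- nd^2
    }
  }
  diag(d2) <- 0
  d2
}

# Pair-sum sums of squares and variance components for a (possibly
# one-level) hierarchical AMOVA. pop/grp are per-individual label vectors
# aligned with d2's rows; grp may be NULL for a one-level analysis.
.amovaCore <- function(d2, pop, grp = NULL) {
  N <- nrow(d2)
  ssWithin <- function(f) {
    idx <- split(seq_len(N), f)
    sum(vapply(idx, function(i) sum(d2[i, i, drop = FALSE]) / (2 * length(i)),
               numeric(1)))
  }
  ssTotal <- sum(d2) / (2 * N)
  ssWP <- ssWithin(pop)
  nP <- as.numeric(table(pop)[unique(pop)])
  P <- length(nP)
  twoLevel <- !is.null(grp) && length(unique(grp)) > 1
  if (twoLevel) {
    G <- length(unique(grp))
    ssWG <- ssWithin(grp)
    ssAP <- ssWG - ssWP
    ssAG <- ssTotal - ssWG
    df <- c(among_groups = G - 1, among_populations = P - G,
            within_populations = N - P, total = N - 1)
    popGrp <- tapply(as.character(grp), as.character(pop), `[`, 1)
    nG <- tapply(as.numeric(table(pop)), popGrp[names(table(pop))], sum)
    sumNp2 <- sum(as.numeric(table(pop))^2)
    sumNp2byG <- tapply(as.numeric(table(pop))^2, popGrp[names(table(pop))], sum)
    # Excoffier weighted-size coefficients for unbalanced designs
    nDblPrime <- (sum(sumNp2byG / nG) - sumNp2 / N) / (G - 1)
    nTriPrime <- (N - sum(nG^2) / N) / (G - 1)
    Vc <- if (N > P) ssWP / (N - P) else 0
    Vb <- if (P > G) {
      nPrime <- (N - sum(sumNp2byG / nG)) / (P - G)
      (ssAP / (P - G) - Vc) / nPrime
    } else 0     # every group holds a single population
    msAG <- ssAG / (G - 1)
    Va <- (msAG - Vc - nDblPrime * Vb) / nTriPrime
    total <- Va + Vb + Vc
    phi <- c(
      phiCT = if (isTRUE(total > 0)) Va / total else NA_real_,
      phiSC = if (isTRUE(Vb + Vc > 0)) Vb / (Vb + Vc) else NA_real_,
      phiST = if (isTRUE(total > 0)) (Va + Vb) / total else NA_real_)
    list(df = df,
         ss = c(among_groups = ssAG, among_populations = ssAP,
                within_populations = ssWP, total = ssTotal),
         v = c(Va = Va, Vb = Vb, Vc = Vc), phi = phi)
  } else {
    ssAP <- ssTotal - ssWP
    df <- c(among_populations = P - 1, within_populations = N - P,
            total = N - 1)
    Vc <- if (N > P) ssWP / (N - P) else 0
    n1 <- (N - sum(as.numeric(table(pop))^2) / N) / (P - 1)
    Vb <- (ssAP / (P - 1) - Vc) / n1
    total <- Vb + Vc
    st <- if (isTRUE(total > 0)) Vb / total else NA_real_
    list(df = df,
         ss = c(among_populations = ssAP, within_populations = ssWP,
                total = ssTotal),
         v = c(Va = 0, Vb = Vb, Vc = Vc),
         phi = c(phiCT = NA_real_, phiSC = st, phiST = st))
  }
}

#' Hierarchical analysis of molecular variance (AMOVA)
#'
#' Partitions squared pairwise distances among groups, among populations
#' within groups, and within populations, via pair-sum sums of squares;
#' variance components use the standard weighted-size coefficients for
#' unbalanced designs, and the Phi fixation indices derive from the
#' components (PhiST = (Va+Vb)/(Va+Vb+Vc)). Significance is assessed by
#' non-parametric permutation with the three standard two-level schemes:
#' individuals among populations ignoring groups (PhiST), individuals among
#' populations within groups (PhiSC), and whole populations among groups
#' (PhiCT). p-values are `(k+1)/(nPerm+1)` with `k` the number of permuted
#' statistics greater than or equal to the observed one, so a statistic
#' exceeding all 1000 permuted values reports p = 1/1001 < 0.001.
#'
#' @param d2 Squared-distance matrix from [distanceMatrix()].
#' @param populations Named character, record id -> population code, covering
#'   all rows of `d2`.
#' @param groups Named character, population code -> group label; `NULL` (or
#'   a single group) for a one-level AMOVA, in which case PhiCT is undefined
#'   and PhiSC equals PhiST.
#' @param nPerm Number of permutations (0 skips the tests).
#' @param seed Integer seed for the permutation RNG, or `NULL`.
#' @return An [AmovaResult-class].
#' @export
amova <- function(d2, populations, groups = NULL, nPerm = 1000, seed = NULL) {
  if (!is.matrix(d2) || nrow(d2) != ncol(d2)) fail("d2 must be a square matrix")
  if (max(abs(d2 - t(d2))) > 1e-9) fail("d2 must be symmetric")
  if (any(diag(d2) != 0)) fail("d2 must have a zero diagonal")
  ids <- rownames(d2)
  if (is.null(ids)) fail("d2 must be labeled by record id")
  if (!all(ids %in% names(populations)))
    fail("every record needs a population label")
  pop <- as.character(populations[ids])
  if (length(unique(pop)) < 2) fail("need at least 2 populations")
  grp <- NULL
  if (!is.null(groups)) {
    if (!all(unique(pop) %in% names(groups)))
      fail("every population needs a group label for a two-level AMOVA")
    grp <- as.character(groups[pop])
  }
  obs <- .amovaCore(d2, pop, grp)
  twoLevel <- !is.null(grp) && length(unique(grp)) > 1
  N <- nrow(d2)
  pvals <- c(phiCT = NA_real_, phiSC = NA_real_, phiST = NA_real_)
  degenerate <- !any(obs$v > 0) || sum(obs$v) <= 0
  if (nPerm > 0 && !degenerate) {
    withSeed(seed, {
      geq <- function(stat, ref) !is.na(stat) && !is.na(ref) &&
        stat >= ref - 1e-12
      kST <- 0L; kSC <- 0L; kCT <- 0L
      for (r in seq_len(nPerm)) {
        # PhiST: individuals among populations ignoring groups
        prm <- sample.int(N)
        stat <- .amovaCore(d2[prm, prm, drop = FALSE], pop, grp)$phi[["phiST"]]
        if (geq(stat, obs$phi[["phiST"]])) kST <- kST + 1L
        if (twoLevel) {
          # PhiSC: individuals among populations within groups
          prm2 <- seq_len(N)
          for (g in unique(grp)) {
            i <- which(grp == g)
            prm2[i] <- i[sample.int(length(i))]
          }
          stat <- .amovaCore(d2[prm2, prm2, drop = FALSE], pop, grp)$phi[["phiSC"]]
          if (geq(stat, obs$phi[["phiSC"]])) kSC <- kSC + 1L
          # PhiCT: whole populations among groups
          upop <- unique(pop)
          popGrp <- vapply(upop, function(p) grp[match(p, pop)], character(1))
          permPopGrp <- stats::setNames(popGrp[sample.int(length(upop))], upop)
          stat <- .amovaCore(d2, pop, as.character(permPopGrp[pop]))$phi[["phiCT"]]
          if (geq(stat, obs$phi[["phiCT"]])) kCT <- kCT + 1L
        }
      }
      pvals[["phiST"]] <- (kST + 1) / (nPerm + 1)
      if (twoLevel) {
        pvals[["phiSC"]] <- (kSC + 1) / (nPerm + 1)
        pvals[["phiCT"]] <- (kCT + 1) / (nPerm + 1)
      }
    })
  }
  totalV <- sum(obs$v)
  pct <- if (totalV > 0) 100 * obs$v / totalV else rep(NA_real_, 3)
  names(pct) <- names(obs$v)
  methods::new("AmovaResult",
               df = obs$df, ss = obs$ss, varianceComponents = obs$v,
               percentages = pct, phi = obs$phi, pValues = pvals,
               nPermutations = as.integer(nPerm),
               seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
}

#' AMOVA table as a data frame
#'
#' Mirrors the standard AMOVA table columns: source of variation, degrees of
#' freedom, sum of squares, variance component, percentage of variation and
#' fixation index.
#'
#' @param result An [AmovaResult-class].
#' @return data.frame.
#' @export
amovaTable <- function(result) {
  stopifnot(methods::is(result, "AmovaResult"))
  strata <- setdiff(names(result@df), "total")
  srcName <- c(among_groups = "Among groups",
               among_populations = "Among populations",
               within_populations = "Within populations")
  comp <- result@varianceComponents
  compBy <- c(among_groups = "Va", among_populations = "Vb",
              within_populations = "Vc")
  phiBy <- c(among_groups = "phiCT", among_populations = "phiSC",
             within_populations = "phiST")
  if (!"among_groups" %in% strata)
    phiBy["among_populations"] <- "phiST"
  data.frame(
    source = c(srcName[strata], "Total"),
    df = unname(c(result@df[strata], result@df[["total"]])),
    sum_of_squares = unname(c(result@ss[strata], result@ss[["total"]])),
    variance_component = c(unname(comp[compBy[strata]]), sum(comp)),
    percentage = c(unname(result@percentages[compBy[strata]]), NA),
    fixation_index = c(unname(result@phi[phiBy[strata]]), NA),
    p_value = c(unname(result@pValues[phiBy[strata]]), NA),
    stringsAsFactors = FALSE)
}
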