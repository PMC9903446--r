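#' Neighbor-joining starting tree
#'
#' Standard neighbor joining (via [ape::nj()]) with negative branch lengths
#' clamped to zero. Tie-breaking is deterministic given the label order of
#' the input matrix.
#'
#' @param d Symmetric distance matrix (plain distances, not squared) with
#'   labels, or a `dist` object; >= 3 labels required.
#' @return A `phylo` tree with branch lengths.
#' @export
njTree <- function(d) {
  if (is.matrix(d)) d <- stats::as.dist(d)
  if (attr(d, "Size") < 3) fail("neighbor joining needs at least 3 labels")
  tr <- ape::nj(d)
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' Pairwise distances from an alignment
#'
#' Proportion of differing sites (missing states excluded pairwise) or its
#' Jukes-Cantor correction; used to seed neighbor joining.
#'
#' @param alignment Equal-length named sequences.
#' @param model `"JC69"` or `"raw"`.
#' @return Symmetric labeled distance matrix.
#' @export
alignmentDistances <- function(alignment, model = c("JC69", "raw")) {
  model <- match.arg(model)
  m <- asAlignmentMatrix(alignment)
  n <- nrow(m)
  miss <- isMissingState(m) | m == .GAP_CHAR
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  if (n > 1) for (i in 1:(n - 1)) for (j in (i + 1):n) {
    ok <- !miss[i, ] & !miss[j, ]
    p <- if (any(ok)) mean(m[i, ok] != m[j, ok]) else 0
    if (model == "JC69")
      p <- if (p >= 0.749) 5 else -0.75 * log(1 - 4 * p / 3)
    d[i, j] <- d[j, i] <- p
  }
  d
}

# One full pass of per-edge scalar branch-length optimization (bounded
# Brent via optimize); only improvements are kept, so the log-likelihood is
# non-decreasing.
.optimizeBranches <- function(phy, prep, eig, current, tol = 1e-6,
                              maxLen = 10) {
  for (i in seq_along(phy$edge.length)) {
    f <- function(x) {
      phy$edge.length[i] <- x
      .pruneLogLik(phy, prep, eig)
    }
    opt <- stats::optimize(f, interval = c(0, maxLen), maximum = TRUE,
                           tol = tol)
    if (opt$objective > current) {
      phy$edge.length[i] <- opt$maximum
      current <- opt$objective
    }
  }
  list(phy = phy, logLik = current)
}

# All NNI rearrangements of a (rooted-representation) binary tree: for each
# internal edge (u, v), swap one child subtree of u with each child subtree
# of v. Edge lengths ride with the moved child edges.
.nniNeighbors <- function(phy) {
  nTip <- length(phy$tip.label)
  E <- phy$edge
  out <- list()
  for (i in seq_len(nrow(E))) {
    u <- E[i, 1]; v <- E[i, 2]
    if (v <= nTip) next                    # internal edges only
    cOpts <- E[E[, 1] == u, 2]
    cOpts <- cOpts[cOpts != v]
    if (!length(cOpts)) next
    cc <- cOpts[1]
    ys <- E[E[, 1] == v, 2]
    for (y in ys) {
      E2 <- E
      E2[E2[, 1] == u & E2[, 2] == cc, 1] <- v
      E2[E[, 1] == v & E[, 2] == y, 1] <- u
      cand <- phy
      cand$edge <- E2
      attr(cand, "order") <- NULL      # cached edge order is stale now
      out[[length(out) + 1L]] <- stats::reorder(cand, "postorder")
    }
  }
  out
}

#' Maximum-likelihood tree search under HKY85
#'
#' Hill climbing from a starting tree: alternates (a) per-edge branch-length
#' optimization by bounded scalar maximization (tolerance 1e-6), (b) the
#' same for the transition/transversion ratio kappa, and (c) evaluation of
#' all nearest-neighbor-interchange rearrangements, accepting the best
#' improving move; the search stops when no move improves the
#' log-likelihood by more than 1e-8. Base frequencies are the empirical
#' frequencies of the alignment; kappa starts at 4. The log-likelihood
#' never decreases and the result is at least as good as the start tree.
#'
#' @param alignment Equal-length named sequences.
#' @param start Starting `phylo` tree over the alignment labels; defaults to
#'   neighbor joining on Jukes-Cantor distances.
#' @param optimizeKappa Optimize kappa (else keep `kappa`).
#' @param optimizeTopology Perform NNI rearrangements.
#' @param kappa Initial transition/transversion ratio.
#' @param maxIter Maximum outer iterations.
#' @return A [PhyloFit-class].
#' @export
mlSearch <- function(alignment, start = NULL, optimizeKappa = TRUE,
                     optimizeTopology = TRUE, kappa = 4, maxIter = 20) {
  m <- asAlignmentMatrix(alignment)
  if (is.null(start))
    start <- njTree(alignmentDistances(m, "JC69"))
  stopifnot(inherits(start, "phylo"))
  phy <- stats::reorder(ape::unroot(start), "postorder")
  if (is.null(phy$edge.length)) phy$edge.length <- rep(0.05, nrow(phy$edge))
  phy$edge.length[phy$edge.length < 0] <- 0
  freqs <- baseFrequencies(m)
  prep <- .makePartials(m, phy$tip.label)
  kap <- kappa
  eig <- .hkyEigen(phyloModel(kap, freqs))
  ll <- .pruneLogLik(phy, prep, eig)
  for (iter in seq_len(maxIter)) {
    llBefore <- ll
    bl <- .optimizeBranches(phy, prep, eig, ll)
    phy <- bl$phy; ll <- bl$logLik
    if (optimizeKappa) {
      f <- function(lk) {
        e <- .hkyEigen(phyloModel(exp(lk), freqs))
        .pruneLogLik(phy, prep, e)
      }
      opt <- stats::optimize(f, interval = log(c(0.05, 50)), maximum = TRUE,
                             tol = 1e-6)
      if (opt$objective > ll) {
        kap <- exp(opt$maximum)
        eig <- .hkyEigen(phyloModel(kap, freqs))
        ll <- opt$objective
      }
    }
    if (optimizeTopology) {
      cands <- .nniNeighbors(phy)
      if (length(cands)) {
        # NNI does not renumber tips, so the site-pattern partials carry over
        cll <- vapply(cands, function(tr) .pruneLogLik(tr, prep, eig),
                      numeric(1))
        best <- which.max(cll)
        if (cll[best] > ll + 1e-8) {
          phy <- stats::reorder(cands[[best]], "postorder")
          ll <- cll[best]
          next
        }
      }
    }
    if (ll - llBefore <= 1e-8) break
  }
  methods::new("PhyloFit", tree = phy, logLik = ll,
               model = phyloModel(kap, freqs), supports = numeric(0))
}

#' Bootstrap supports for the bipartitions of a tree
#'
#' Site-resampled replicates, each run through neighbor joining and a
#' reduced maximum-likelihood pass (branch lengths only; the replicate
#' topology is the neighbor-joining one). Supports are the fraction of
#' replicate trees containing each bipartition of the point-estimate tree.
#'
#' @param alignment Equal-length named sequences.
#' @param nReps Number of bootstrap replicates (>= 1).
#' @param seed Integer seed or `NULL`.
#' @param tree Point-estimate tree (`phylo` or [PhyloFit-class]); computed
#'   by [mlSearch()] when absent.
#' @param refine `"branch_lengths"` re-optimizes replicate branch lengths
#'   under HKY85 (topology unchanged); `"none"` keeps the NJ lengths.
#' @return The point tree as a [PhyloFit-class] with `supports` filled: one
#'   fraction per internal node (ape node order, root `NA`).
#' @export
bootstrapSupports <- function(alignment, nReps = 100, seed = NULL,
                              tree = NULL, refine = c("branch_lengths", "none")) {
  refine <- match.arg(refine)
  if (nReps < 1) fail("nReps must be >= 1")
  m <- asAlignmentMatrix(alignment)
  fit <- if (is.null(tree)) mlSearch(m)
         else if (methods::is(tree, "PhyloFit")) tree
         else methods::new("PhyloFit", tree = tree,
                           logLik = NA_real_,
                           model = phyloModel(4, baseFrequencies(m)),
                           supports = numeric(0))
  point <- fit@tree
  reps <- withSeed(seed, {
    lapply(seq_len(nReps), function(r) {
      cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
      mb <- m[, cols, drop = FALSE]
      tr <- njTree(alignmentDistances(mb, "JC69"))
      if (refine == "branch_lengths") {
        rfit <- mlSearch(mb, start = tr, optimizeTopology = FALSE,
                         maxIter = 2)
        tr <- rfit@tree
      }
      tr
    })
  })
  counts <- ape::prop.clades(point, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0
  fit@supports <- counts / nReps
  fit
}
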