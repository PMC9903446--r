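#' Construct an HKY85 model
#'
#' @param kappa Transition/transversion rate ratio (> 0).
#' @param freqs Base frequencies in the order A, C, G, T; must be positive
#'   and sum to 1.
#' @return A [PhyloModel-class].
#' @export
phyloModel <- function(kappa = 4, freqs = rep(0.25, 4)) {
  methods::new("PhyloModel", kappa = as.numeric(kappa),
               freqs = as.numeric(freqs))
}

#' HKY85 rate matrix, scaled to unit mean substitution rate
#'
#' Off-diagonal rates are `kappa * pi_j` for transitions (A<->G, C<->T) and
#' `pi_j` for transversions; the matrix is rescaled so that
#' `-sum(pi_i * Q[i,i]) = 1`, making branch lengths expected substitutions
#' per site.
#'
#' @param model A [PhyloModel-class].
#' @return 4x4 numeric matrix (rows/cols A, C, G, T).
#' @export
hkyRateMatrix <- function(model) {
  methods::validObject(model)
  pi <- model@freqs
  k <- model@kappa
  bases <- c("A", "C", "G", "T")
  Q <- matrix(0, 4, 4, dimnames = list(bases, bases))
  transition <- matrix(FALSE, 4, 4)
  transition[1, 3] <- transition[3, 1] <- TRUE  # A <-> G
  transition[2, 4] <- transition[4, 2] <- TRUE  # C <-> T
  for (i in 1:4) for (j in 1:4) if (i != j)
    Q[i, j] <- pi[j] * if (transition[i, j]) k else 1
  diag(Q) <- -rowSums(Q)
  Q / sum(pi * -diag(Q))
}

# Eigendecomposition of the reversible rate matrix via its symmetrized form
# (numerically stable); cached per model by callers.
.hkyEigen <- function(model) {
  Q <- hkyRateMatrix(model)
  pi <- model@freqs
  sq <- sqrt(pi)
  S <- diag(sq) %*% Q %*% diag(1 / sq)
  e <- eigen((S + t(S)) / 2, symmetric = TRUE)
  list(right = diag(1 / sq) %*% e$vectors,
       left = t(e$vectors) %*% diag(sq),
       values = e$values, pi = pi)
}

# P(t) = exp(Qt) from the cached eigendecomposition.
.hkyProb <- function(eig, t) {
  P <- eig$right %*% (exp(eig$values * t) * eig$left)
  P[P < 0] <- 0
  P
}

#' HKY85 transition probability matrix
#'
#' @param model A [PhyloModel-class].
#' @param t Branch length in expected substitutions per site (>= 0).
#' @return 4x4 stochastic matrix P(t) (rows A, C, G, T sum to 1).
#' @export
hkyTransitionProb <- function(model, t) {
  if (t < 0) fail("branch length must be >= 0")
  P <- .hkyProb(.hkyEigen(model), t)
  dimnames(P) <- list(c("A", "C", "G", "T"), c("A", "C", "G", "T"))
  P
}

# Alignment -> list(partials = per-tip 4 x npattern 0/1 matrices,
# weights = pattern multiplicities). Missing states (N/?/-/ambiguity)
# marginalize over all four bases.
.makePartials <- function(aln, tipLabels) {
  m <- asAlignmentMatrix(aln)
  if (is.null(rownames(m))) fail("alignment sequences must be named")
  if (!all(tipLabels %in% rownames(m)))
    fail("alignment is missing tip(s): %s",
         paste(setdiff(tipLabels, rownames(m)), collapse = ", "))
  m <- m[tipLabels, , drop = FALSE]
  key <- apply(m, 2, paste, collapse = "")
  patterns <- which(!duplicated(key))
  weights <- as.numeric(table(factor(key, levels = key[patterns])))
  bases <- c("A", "C", "G", "T")
  partials <- lapply(seq_along(tipLabels), function(i) {
    out <- matrix(1, 4, length(patterns))
    idx <- match(m[i, patterns], bases)
    known <- !is.na(idx)
    out[, known] <- 0
    out[cbind(idx[known], which(known))] <- 1
    out
  })
  list(partials = partials, weights = weights)
}

# Felsenstein pruning over site patterns. `prep` from .makePartials with
# tipLabels = phy$tip.label.
.pruneLogLik <- function(phy, prep, eig) {
  phy <- stats::reorder(phy, "postorder")
  E <- phy$edge
  el <- phy$edge.length
  nTip <- length(phy$tip.label)
  buf <- vector("list", nTip + phy$Nnode)
  buf[seq_len(nTip)] <- prep$partials
  for (i in seq_len(nrow(E))) {
    P <- .hkyProb(eig, el[i])
    contrib <- P %*% buf[[E[i, 2]]]
    par <- E[i, 1]
    buf[[par]] <- if (is.null(buf[[par]])) contrib else buf[[par]] * contrib
  }
  lik <- colSums(eig$pi * buf[[nTip + 1L]])
  sum(prep$weights * log(lik))
}

#' Log-likelihood of an alignment on a tree under HKY85
#'
#' Felsenstein pruning over site patterns, with missing states (`N`, `?`,
#' gaps) marginalized over all four bases. Branch lengths are expected
#' substitutions per site. The result is invariant to leaf reordering and to
#' the (arbitrary) rooting of the unrooted tree, by reversibility.
#'
#' @param tree A `phylo` object with branch lengths, or a [PhyloFit-class].
#' @param alignment Equal-length named sequences covering the tip labels.
#' @param model A [PhyloModel-class].
#' @return Numeric log-likelihood (sum over sites).
#' @export
hky85LogLik <- function(tree, alignment, model) {
  if (methods::is(tree, "PhyloFit")) tree <- tree@tree
  stopifnot(inherits(tree, "phylo"))
  methods::validObject(model)
  if (is.null(tree$edge.length)) fail("tree must have branch lengths")
  prep <- .makePartials(alignment, tree$tip.label)
  .pruneLogLik(tree, prep, .hkyEigen(model))
}

#' Empirical base frequencies of an alignment
#'
#' Counts of A, C, G, T across the alignment; missing states and gaps are
#' excluded. A small floor keeps all four frequencies positive.
#'
#' @param alignment Sequences (any form accepted by the likelihood).
#' @return Numeric length 4 (A, C, G, T), summing to 1.
#' @export
baseFrequencies <- function(alignment) {
  m <- asAlignmentMatrix(alignment)
  counts <- vapply(c("A", "C", "G", "T"), function(b) sum(m == b), numeric(1))
  counts <- pmax(counts, 1e-6)
  counts / sum(counts)
}
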