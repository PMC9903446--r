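# Independent oracles used by unit and acceptance tests. These deliberately
# avoid the package's own code paths: the likelihood oracle sums over all
# ancestral state assignments with matrix exponentials, and the AMOVA oracle
# evaluates the definitional pair-sum formulas with explicit loops.

ORACLE_BASES <- c("A", "C", "G", "T")

# exp(Qt) via Matrix::expm, with Q built here from first principles
oracleHkyP <- function(kappa, freqs, t) {
  Q <- matrix(0, 4, 4)
  rate <- matrix(1, 4, 4)
  rate[1, 3] <- rate[3, 1] <- kappa
  rate[2, 4] <- rate[4, 2] <- kappa
  for (i in 1:4) for (j in 1:4) if (i != j) Q[i, j] <- freqs[j] * rate[i, j]
  diag(Q) <- -rowSums(Q)
  Q <- Q / sum(freqs * -diag(Q))
  as.matrix(Matrix::expm(Q * t))
}

# Exhaustive log-likelihood: sum over all 4^Nnode ancestral assignments.
# Missing states (anything not A/C/G/T) marginalize over all bases.
oracleLogLik <- function(tree, aln, kappa, freqs) {
  E <- tree$edge
  nTip <- length(tree$tip.label)
  nNode <- tree$Nnode
  Pm <- lapply(seq_len(nrow(E)), function(i)
    oracleHkyP(kappa, freqs, tree$edge.length[i]))
  mat <- do.call(rbind, strsplit(aln[tree$tip.label], ""))
  S <- ncol(mat)
  total <- 0
  grid <- as.matrix(expand.grid(rep(list(1:4), nNode)))
  for (s in seq_len(S)) {
    obs <- match(mat[, s], ORACLE_BASES)   # NA = missing
    lik <- 0
    for (g in seq_len(nrow(grid))) {
      anc <- grid[g, ]
      tipStates <- lapply(seq_len(nTip), function(i)
        if (is.na(obs[i])) 1:4 else obs[i])
      tipCombos <- as.matrix(expand.grid(tipStates))
      for (tc in seq_len(nrow(tipCombos))) {
        st <- c(as.integer(tipCombos[tc, ]), anc)
        p <- freqs[st[nTip + 1]]
        for (i in seq_len(nrow(E))) p <- p * Pm[[i]][st[E[i, 1]], st[E[i, 2]]]
        lik <- lik + p
      }
    }
    total <- total + log(lik)
  }
  total
}

# Definitional two-level AMOVA: pair-sum sums of squares and Excoffier
# weighted-size coefficients, written with explicit loops.
oracleAmova <- function(d2, pop, grpOfPop) {
  ids <- rownames(d2)
  N <- length(ids)
  grp <- unname(grpOfPop[pop])
  pairSum <- function(keep) {
    s <- 0
    idx <- which(keep)
    if (length(idx) < 2) return(0)
    for (a in seq_along(idx)[-length(idx)])
      for (b in (a + 1):length(idx))
        s <- s + d2[idx[a], idx[b]]
    s
  }
  ssTotal <- pairSum(rep(TRUE, N)) / N
  pops <- unique(pop)
  ssWP <- 0
  for (p in pops) ssWP <- ssWP + pairSum(pop == p) / sum(pop == p)
  grps <- unique(grp)
  ssWG <- 0
  for (g in grps) ssWG <- ssWG + pairSum(grp == g) / sum(grp == g)
  ssAP <- ssWG - ssWP
  ssAG <- ssTotal - ssWG
  P <- length(pops); G <- length(grps)
  nP <- sapply(pops, function(p) sum(pop == p))
  gOf <- sapply(pops, function(p) grp[match(p, pop)])
  nG <- sapply(grps, function(g) sum(grp == g))
  sumA <- 0
  for (g in grps) sumA <- sumA + sum(nP[gOf == g]^2) / nG[g]
  nPrime <- (N - sumA) / (P - G)
  nDbl <- (sumA - sum(nP^2) / N) / (G - 1)
  nTri <- (N - sum(nG^2) / N) / (G - 1)
  Vc <- ssWP / (N - P)
  Vb <- (ssAP / (P - G) - Vc) / nPrime
  Va <- (ssAG / (G - 1) - Vc - nDbl * Vb) / nTri
  list(ss = c(ssAG, ssAP, ssWP, ssTotal),
       df = c(G - 1, P - G, N - P, N - 1),
       v = c(Va = Va, Vb = Vb, Vc = Vc),
       phi = c(phiCT = Va / (Va + Vb + Vc),
               phiSC = Vb / (Vb + Vc),
               phiST = (Va + Vb) / (Va + Vb + Vc)))
}

randomDnaString <- function(n) paste(sample(ORACLE_BASES, n, TRUE), collapse = "")
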