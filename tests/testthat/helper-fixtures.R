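# Shared fixtures, built in code.

# tiny complete-data counts object
tinyCounts <- function() {
  alleleCounts(
    ref = cbind(P1 = c(2L, 0L, 5L), P2 = c(8L, 1L, 5L)),
    n   = cbind(P1 = c(10L, 10L, 10L), P2 = c(10L, 10L, 10L)))
}

# noiseless S matrix for a tree: entries are the model expectations
noiselessS <- function(tree) {
  tl <- tipLabels(tree)
  K <- length(tl)
  S <- matrix(NA_real_, K, K, dimnames = list(tl, tl))
  for (i in seq_len(K)) for (j in seq_len(K))
    if (i != j) S[i, j] <- expectedS(tree, tl[i], tl[j])
  S
}

# random rooted binary tree over given tips with theta in [lo, hi]
randomBinaryTree <- function(tips, lo = 0.02, hi = 0.3) {
  K <- length(tips)
  parent <- c(0L, rep(1L, K))
  labels <- c("0", tips)
  active <- 2:(K + 1)
  while (length(active) > 2) {
    pick <- sample(seq_along(active), 2)
    newn <- length(parent) + 1L
    parent <- c(parent, 1L)
    labels <- c(labels, paste0("i", newn))
    parent[active[pick]] <- newn
    active <- c(active[-pick], newn)
  }
  theta <- c(NA, stats::runif(length(parent) - 1, lo, hi))
  populationTree(parent, labels, theta)
}

# exhaustive minimal-xi topology search over all rooted binary trees
# (oracle for the two-phase heuristic; phangorn enumerates topologies)
exhaustiveBestXi <- function(S, clipEps = 1e-12) {
  tl <- colnames(S)
  all <- phangorn::allTrees(length(tl), rooted = TRUE, tip.label = tl)
  best <- NULL
  bestXi <- Inf
  for (i in seq_along(all)) {
    phy <- all[[i]]          # [[ expands the shared multiPhylo tip labels
    phy$edge.length <- rep(0.5, nrow(phy$edge))
    tree <- phyloToTree(phy)
    fit <- fitThetas(tree, S, clipEps = clipEps)
    if (fit@xi < bestXi) {
      bestXi <- fit@xi
      best <- fit
    }
  }
  list(fit = best, xi = bestXi)
}
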