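# Joint inference of tree topology and branch parameters by minimizing the
# logarithmic least-squares objective
#   xi(beta) = sum over ordered tip pairs (k, k') of
#              (log S_kk' - sum_{q in R(kk')} beta_q)^2,   beta_q <= 0,
# solved as non-negative least squares in gamma = -beta.  The search runs a
# hierarchical clustering phase from the star tree (K - 2 merges, each
# chosen to minimize xi) followed by an improvement phase that repeatedly
# tries to relocate each tip onto every other branch of the tree.
#
# Internal representation: a parent-pointer vector over 2K - 1 nodes in
# which tip t of the S matrix is node t + 1 (node 1 is the initial root;
# the improvement phase may move the root elsewhere).

# ordered pair rows of the least-squares system from a clipped S matrix
.rowsFromS <- function(Smat, clipEps = 1e-12) {
  K <- ncol(Smat)
  ij <- expand.grid(i = seq_len(K), j = seq_len(K))
  ij <- ij[ij$i != ij$j, ]
  s <- Smat[cbind(ij$i, ij$j)]
  keep <- is.finite(s)
  s <- pmin(pmax(s[keep], clipEps), 1)
  list(i = ij$i[keep], j = ij$j[keep], y = -log(s), K = K,
       nDropped = sum(!keep))
}

# K x nNodes logical matrix: does tip t's root path include node (branch) q?
.pathMat <- function(parent, tipNodes) {
  M <- matrix(FALSE, length(tipNodes), length(parent))
  for (t in seq_along(tipNodes)) {
    node <- tipNodes[t]
    while (parent[node] != 0L) {
      M[t, node] <- TRUE
      node <- parent[node]
    }
  }
  M
}

# fit gamma >= 0 for one candidate topology; rows index tip positions
.fitCore <- function(parent, tipNodes, rowsI, rowsJ, y) {
  branches <- which(parent != 0L)
  M <- .pathMat(parent, tipNodes)
  X <- M[rowsI, branches, drop = FALSE] * (1 - M[rowsJ, branches, drop = FALSE])
  res <- .nnlsCpp(X, y)
  list(xi = res$rss, gamma = res$gamma, branches = branches,
       iterations = res$iterations)
}

.XI_REL_TOL <- 1e-12

.betterXi <- function(xi, best) {
  if (!is.finite(best)) return(is.finite(xi))
  xi < best - .XI_REL_TOL * max(1, abs(best))
}

# clustering phase on the internal representation; returns parent vector
.clusterCore <- function(rows, tipKeys) {
  K <- rows$K
  parent <- c(0L, rep(1L, K))
  tipNodes <- 2:(K + 1)
  key <- c("", tipKeys)                 # per-node minimal descendant label
  nFits <- 0L
  for (step in seq_len(max(K - 2L, 0L))) {
    ch <- which(parent == 1L)
    ch <- ch[order(key[ch])]
    nc <- length(ch)
    bestXi <- Inf
    bestPair <- NULL
    newn <- length(parent) + 1L
    for (ai in seq_len(nc - 1L)) for (bi in (ai + 1L):nc) {
      p2 <- c(parent, 1L)
      p2[ch[ai]] <- p2[ch[bi]] <- newn
      xi <- .fitCore(p2, tipNodes, rows$i, rows$j, rows$y)$xi
      nFits <- nFits + 1L
      if (.betterXi(xi, bestXi)) {
        bestXi <- xi
        bestPair <- c(ch[ai], ch[bi])
      }
    }
    parent <- c(parent, 1L)
    parent[bestPair] <- newn
    key[newn] <- min(key[bestPair])
  }
  list(parent = parent, nFits = nFits)
}

# tip-relocation improvement phase; tips visited in seeded random order
.improveCore <- function(parent, rows, passesCap) {
  K <- rows$K
  tipNodes <- 2:(K + 1)
  nFits <- 0L
  passes <- 0L
  for (pass in seq_len(passesCap)) {
    passes <- pass
    changed <- FALSE
    for (t in sample.int(K)) {
      k <- tipNodes[t]
      P <- parent[k]
      sib <- setdiff(which(parent == P), k)
      G <- parent[P]
      curXi <- .fitCore(parent, tipNodes, rows$i, rows$j, rows$y)$xi
      nFits <- nFits + 1L
      bestXi <- curXi
      bestParent <- NULL
      for (v in seq_along(parent)) {
        if (v == k || v == P || v == sib) next
        p2 <- parent
        p2[sib] <- G                    # suppress k's old parent
        p2[P] <- p2[v]                  # re-insert it above v
        p2[v] <- P
        xi <- .fitCore(p2, tipNodes, rows$i, rows$j, rows$y)$xi
        nFits <- nFits + 1L
        if (.betterXi(xi, bestXi)) {
          bestXi <- xi
          bestParent <- p2
        }
      }
      if (!is.null(bestParent)) {
        parent <- bestParent
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  list(parent = parent, passes = passes, nFits = nFits)
}

# full inference from a (raw or clipped) S matrix; uses the current RNG
# stream for the improvement-phase tip order
.inferFromS <- function(Smat, passesCap = 10L, clipEps = 1e-12) {
  rows <- .rowsFromS(Smat, clipEps)
  K <- rows$K
  cl <- .clusterCore(rows, colnames(Smat))
  im <- .improveCore(cl$parent, rows, passesCap)
  parent <- im$parent
  tipNodes <- 2:(K + 1)
  fit <- .fitCore(parent, tipNodes, rows$i, rows$j, rows$y)
  theta <- rep(NA_real_, length(parent))
  theta[fit$branches] <- -expm1(-fit$gamma)
  labels <- character(length(parent))
  labels[tipNodes] <- colnames(Smat)
  internal <- setdiff(seq_along(parent), tipNodes)
  labels[internal] <- paste0("n", seq_along(internal))
  labels[parent == 0L] <- "0"
  list(parent = parent, labels = labels, theta = theta, xi = fit$xi,
       rowsUsed = length(rows$y), nDropped = rows$nDropped,
       passes = im$passes, nFits = cl$nFits + im$nFits + 1L)
}

.asPopulationTree <- function(core) {
  populationTree(core$parent, core$labels, core$theta)
}

# map a PopulationTree onto the internal representation so that tip t of
# the S matrix is node t + 1
.treeToCore <- function(tree, sLabels) {
  tl <- tipLabels(tree)
  if (!setequal(tl, sLabels))
    stop("tree tips must match the S matrix labels")
  tips <- .tipNodes(tree)
  K <- length(tips)
  N <- length(tree@parent)
  newIdx <- integer(N)
  newIdx[tips[match(sLabels, tree@labels[tips])]] <- 2:(K + 1)
  rest <- setdiff(seq_len(N), tips)
  root <- .rootNode(tree)
  rest <- c(root, setdiff(rest, root))
  newIdx[rest] <- c(1L, if (N > K + 1) (K + 2):N)
  parent <- integer(N)
  mapped <- integer(N)
  nz <- tree@parent != 0L
  mapped[nz] <- newIdx[tree@parent[nz]]
  parent[newIdx] <- mapped
  labels <- character(N)
  labels[newIdx] <- tree@labels
  theta <- rep(NA_real_, N)
  theta[newIdx] <- tree@theta
  list(parent = parent, labels = labels, theta = theta, K = K)
}

#' Build the least-squares design system for a tree and S matrix
#'
#' One row per ordered tip pair (k, k') with a defined S value; the 0/1
#' design column for branch q is 1 exactly when q is ancestral to k but not
#' to k'.  The response is `y = -log S >= 0`, so the solve runs over
#' `gamma = -beta >= 0`.
#'
#' @param tree a [PopulationTree-class] whose tips match `S`'s labels.
#' @param S K x K matrix of (raw or clipped) S values with unit labels as
#'   dimnames; `NA` marks undefined pairs, whose rows are dropped.
#' @param clipEps lower clip bound applied to S before taking logs.
#' @return `list(X, y, rows)` with `rows` a data frame of the retained
#'   ordered pairs.
#' @export
designSystem <- function(tree, S, clipEps = 1e-12) {
  core <- .treeToCore(tree, colnames(S))
  rows <- .rowsFromS(S, clipEps)
  branches <- which(core$parent != 0L)
  M <- .pathMat(core$parent, 2:(core$K + 1))
  X <- M[rows$i, branches, drop = FALSE] *
    (1 - M[rows$j, branches, drop = FALSE])
  colnames(X) <- core$labels[branches]
  list(X = X, y = rows$y,
       rows = data.frame(k = colnames(S)[rows$i], kp = colnames(S)[rows$j],
                         stringsAsFactors = FALSE))
}

#' Fit branch parameters of a fixed topology
#'
#' Minimizes the logarithmic least-squares objective over `gamma >= 0`
#' (Lawson-Hanson non-negative least squares) for the given topology and
#' returns the tree with `theta = 1 - exp(-gamma)` on each branch.
#'
#' @inheritParams designSystem
#' @return A [FitResult-class] (tree with fitted theta, objective value
#'   `xi`, diagnostics).
#' @export
fitThetas <- function(tree, S, clipEps = 1e-12) {
  core <- .treeToCore(tree, colnames(S))
  rows <- .rowsFromS(S, clipEps)
  nBranch <- sum(core$parent != 0L)
  if (length(rows$y) < nBranch)
    warning("fewer pair rows than branches; fit is under-determined")
  fit <- .fitCore(core$parent, 2:(core$K + 1), rows$i, rows$j, rows$y)
  theta <- rep(NA_real_, length(core$parent))
  theta[fit$branches] <- -expm1(-fit$gamma)
  new("FitResult",
      tree = populationTree(core$parent, core$labels, theta),
      xi = fit$xi, rowsUsed = length(rows$y),
      diagnostics = list(nDropped = rows$nDropped,
                         iterations = fit$iterations))
}

#' @describeIn fitThetas fitted tree of a FitResult.
#' @export
setMethod("fittedTree", "FitResult", function(x) x@tree)

#' @describeIn fitThetas objective value of a FitResult.
#' @export
setMethod("objectiveXi", "FitResult", function(x) x@xi)

setMethod("show", "FitResult", function(object) {
  cat(sprintf("FitResult: xi = %.6g over %d pair rows\n",
              object@xi, object@rowsUsed))
  show(object@tree)
  invisible(object)
})

#' Clustering phase: build a binary tree by successive pair merges
#'
#' Starts from the star tree (the independent-descent model) and performs
#' K - 2 merge steps; at each step every pair of the root's current
#' children is tried as the next merge (inserting a new ancestral node
#' between them and the root) and the pair minimizing the objective is
#' kept.  Ties (within 1e-12 relative) resolve to the lexicographically
#' smallest label pair, so the phase is deterministic.
#'
#' @param S K x K matrix of S values with unit labels as dimnames.
#' @param labels unit labels (default: `colnames(S)`).
#' @param clipEps lower clip bound for S.
#' @return A binary [PopulationTree-class] with fitted branch parameters.
#' @export
clusterPhase <- function(S, labels = colnames(S), clipEps = 1e-12) {
  colnames(S) <- rownames(S) <- labels
  rows <- .rowsFromS(S, clipEps)
  cl <- .clusterCore(rows, labels)
  fit <- .fitCore(cl$parent, 2:(rows$K + 1), rows$i, rows$j, rows$y)
  theta <- rep(NA_real_, length(cl$parent))
  theta[fit$branches] <- -expm1(-fit$gamma)
  lab <- character(length(cl$parent))
  lab[2:(rows$K + 1)] <- labels
  internal <- setdiff(seq_along(cl$parent), 2:(rows$K + 1))
  lab[internal] <- paste0("n", seq_along(internal))
  lab[cl$parent == 0L] <- "0"
  populationTree(cl$parent, lab, theta)
}

#' Improvement phase: relocate tips to lower the objective
#'
#' Visits the tips in seeded random order; for each tip the current tree is
#' compared against re-inserting the tip's parent on every other branch of
#' the tree (after suppressing the old parent node), and the best placement
#' is kept, the current tree winning ties.  Full passes repeat until a pass
#' changes nothing or `passesCap` is reached.
#'
#' @param tree a binary [PopulationTree-class] (e.g. from [clusterPhase()]).
#' @param S K x K matrix of S values matching the tree's tips.
#' @param seed optional integer seed for the tip visiting order; `NULL`
#'   uses the current RNG stream.
#' @param passesCap maximum number of full passes.
#' @param clipEps lower clip bound for S.
#' @return A [PopulationTree-class] with refitted branch parameters.
#' @export
improvePhase <- function(tree, S, seed = NULL, passesCap = 10L,
                         clipEps = 1e-12) {
  if (!is.null(seed)) set.seed(seed)
  core <- .treeToCore(tree, colnames(S))
  rows <- .rowsFromS(S, clipEps)
  im <- .improveCore(core$parent, rows, passesCap)
  fit <- .fitCore(im$parent, 2:(rows$K + 1), rows$i, rows$j, rows$y)
  theta <- rep(NA_real_, length(im$parent))
  theta[fit$branches] <- -expm1(-fit$gamma)
  lab <- character(length(im$parent))
  lab[2:(rows$K + 1)] <- colnames(S)
  internal <- setdiff(seq_along(im$parent), 2:(rows$K + 1))
  lab[internal] <- paste0("n", seq_along(internal))
  lab[im$parent == 0L] <- "0"
  populationTree(im$parent, lab, theta)
}

#' Joint inference of tree and coancestry matrices from allele counts
#'
#' End-to-end pipeline: per-pair moment sums, the clipped S matrix, the
#' clustering phase, the improvement phase, and the coancestry matrices of
#' the fitted tree.  The S statistics are computed once, in a single pass
#' over the loci; every later step depends only on the K x K summaries.
#'
#' @param acm an [AlleleCounts-class] object (K >= 2 units).
#' @param seed integer seed controlling the improvement-phase tip order.
#' @param passesCap maximum improvement passes.
#' @param clipEps lower clip bound for S.
#' @return `list(fit = FitResult, estimates = CoancestryEstimates)`.
#' @export
inferTree <- function(acm, seed = 1L, passesCap = 10L, clipEps = 1e-12) {
  ps <- pairSums(acm)
  S <- sMatrix(ps, clipEps = clipEps)
  set.seed(seed)
  core <- .inferFromS(S, passesCap = passesCap, clipEps = clipEps)
  tree <- .asPopulationTree(core)
  fit <- new("FitResult", tree = tree, xi = core$xi,
             rowsUsed = core$rowsUsed,
             diagnostics = list(nDropped = core$nDropped,
                                passes = core$passes, nFits = core$nFits,
                                seed = seed))
  list(fit = fit, estimates = coancestryMatrices(tree))
}
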