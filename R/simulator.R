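# Hierarchical beta-drift simulator.  Per site, an ancestral allele
# frequency is drawn from a beta distribution, propagated down the tree by
# conditional beta draws whose mean is the parent frequency and whose
# variance is theta * p * (1 - p), and finally binomially sampled as
# gametes at each tip.  Sites are independent (no linkage).

#' Scenario configuration for the simulator
#'
#' Either give a preset name (`"S1"` to `"S6"`, all on the
#' [scenarioTree()] truth with 25/10/2/25/10/10 gametes per unit and
#' 1e4/1e4/1e4/1e3/1e3/1e2 sites) or set the fields directly.  Any preset
#' field can be overridden.
#'
#' @param name optional preset name.
#' @param tree truth tree (default [scenarioTree()]).
#' @param gametes gametes sampled per unit (scalar or per-unit vector).
#' @param nSites number of sites to simulate per replicate.
#' @param shape length-2 shape parameters of the ancestral beta
#'   distribution (default `c(0.4, 0.4)`).
#' @param alpha optional admixture fraction: the parent node of `admixTip`
#'   draws its frequency as `alpha * p[admixSource] + (1 - alpha) *
#'   p[parent]` before the tip's drift draw.  `NA` disables admixture.
#' @param admixTip,admixSource node labels for the admixture variant
#'   (defaults `"C"` and `"1"`, matching the reference tree).
#' @return A [ScenarioConfig-class] object.
#' @examples
#' scenarioConfig("S4")
#' scenarioConfig("S4", alpha = 0.1)
#' @export
scenarioConfig <- function(name = NULL, tree = scenarioTree(),
                           gametes = NULL, nSites = NULL,
                           shape = c(0.4, 0.4), alpha = NA_real_,
                           admixTip = "C", admixSource = "1") {
  presets <- list(S1 = c(25L, 10000L), S2 = c(10L, 10000L),
                  S3 = c(2L, 10000L), S4 = c(25L, 1000L),
                  S5 = c(10L, 1000L), S6 = c(10L, 100L))
  if (!is.null(name)) {
    if (!name %in% names(presets)) stop("unknown scenario name: ", name)
    if (is.null(gametes)) gametes <- presets[[name]][1]
    if (is.null(nSites)) nSites <- presets[[name]][2]
  } else {
    name <- "custom"
    if (is.null(gametes) || is.null(nSites))
      stop("gametes and nSites are required without a preset name")
  }
  K <- length(tipLabels(tree))
  new("ScenarioConfig", tree = tree,
      gametes = as.integer(rep_len(gametes, K)),
      nSites = as.integer(nSites), shape = as.numeric(shape),
      alpha = as.numeric(alpha), admixTip = admixTip,
      admixSource = admixSource, name = name)
}

setMethod("show", "ScenarioConfig", function(object) {
  cat(sprintf("ScenarioConfig '%s': %d tips, gametes [%s], %d sites\n",
              object@name, length(tipLabels(object@tree)),
              paste(unique(object@gametes), collapse = ","),
              object@nSites))
  if (!is.na(object@alpha))
    cat(sprintf("admixture: parent of %s takes alpha = %g from %s\n",
                object@admixTip, object@alpha, object@admixSource))
  invisible(object)
})

#' Draw child allele frequencies under beta drift
#'
#' Conditional on a parent frequency `p` and drift parameter `theta`, the
#' child frequency is beta-distributed with mean `p` and variance
#' `theta * p * (1 - p)`: shapes `a = p (1 - theta) / theta` and
#' `b = (1 - p)(1 - theta) / theta`.  Degenerate cases are exact:
#' `theta = 0` copies the parent, a fixed parent stays fixed, and
#' `theta = 1` fixes the child at 1 with probability `p`.
#'
#' @param p vector of parent frequencies in `[0, 1]`.
#' @param theta drift parameter in `[0, 1]` (scalar).
#' @return Vector of child frequencies, one per element of `p`.
#' @export
drawChildFreq <- function(p, theta) {
  if (theta < 0 || theta > 1) stop("theta must lie in [0, 1]")
  if (theta == 0) return(p)
  out <- p
  inner <- p > 0 & p < 1
  if (theta == 1) {
    out[inner] <- as.numeric(stats::runif(sum(inner)) < p[inner])
    return(out)
  }
  f <- (1 - theta) / theta
  pi <- p[inner]
  out[inner] <- rbeta(length(pi), pi * f, (1 - pi) * f)
  out
}

# nodes in root-first topological order
.topoOrder <- function(parent) {
  depth <- integer(length(parent))
  for (i in seq_along(parent)) {
    j <- i
    while (parent[j] != 0L) {
      depth[i] <- depth[i] + 1L
      j <- parent[j]
    }
  }
  order(depth)
}

# frequency-level simulation: matrix nSites x nNodes of true frequencies
.simFreqs <- function(config, nSites = config@nSites) {
  tree <- config@tree
  parent <- tree@parent
  p <- matrix(0, nSites, length(parent))
  colnames(p) <- tree@labels
  ord <- .topoOrder(parent)
  root <- ord[1]
  p[, root] <- rbeta(nSites, config@shape[1], config@shape[2])
  admixChild <- if (!is.na(config@alpha))
    .nodeIndex(tree, config@admixTip) else 0L
  admixSrc <- if (!is.na(config@alpha))
    .nodeIndex(tree, config@admixSource) else 0L
  for (node in ord[-1]) {
    pp <- p[, parent[node]]
    if (node == admixChild)
      pp <- config@alpha * p[, admixSrc] + (1 - config@alpha) * pp
    p[, node] <- drawChildFreq(pp, tree@theta[node])
  }
  p
}

# counts-level simulation core, used by simulateReplicate() and the
# evaluation fast path; returns plain matrices restricted to SNV sites
.simCountsCore <- function(config) {
  tree <- config@tree
  freqs <- .simFreqs(config)
  tips <- .tipNodes(tree)
  nSites <- config@nSites
  K <- length(tips)
  ref <- matrix(0L, nSites, K, dimnames = list(NULL, tree@labels[tips]))
  for (t in seq_len(K))
    ref[, t] <- rbinom(nSites, config@gametes[t], freqs[, tips[t]])
  tot <- rowSums(ref)
  keep <- tot > 0L & tot < sum(config@gametes)
  list(ref = ref[keep, , drop = FALSE],
       n = matrix(rep(config@gametes, each = sum(keep)), ncol = K,
                  dimnames = list(NULL, tree@labels[tips])),
       freqs = freqs[keep, , drop = FALSE], nSitesTotal = nSites,
       nSnv = sum(keep))
}

#' Simulate one allele-count replicate
#'
#' Per site: draw the ancestral frequency, propagate it down the tree by
#' beta drift (with the optional admixture mixing applied to the parent
#' frequency of the admixed tip before its draw), sample gametes
#' binomially at each tip, then keep only SNV sites (at least one copy of
#' a minor allele somewhere in the pooled sample; no MAF threshold).
#'
#' @param config a [ScenarioConfig-class] object.
#' @param seed optional integer seed; `NULL` uses the current RNG stream.
#' @return A [SimReplicate-class] object.
#' @export
simulateReplicate <- function(config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sim <- .simCountsCore(config)
  rownames(sim$ref) <- rownames(sim$n) <- paste0("s", seq_len(sim$nSnv))
  new("SimReplicate", counts = alleleCounts(sim$ref, sim$n),
      nodeFreqs = sim$freqs, nSitesTotal = sim$nSitesTotal,
      nSnv = as.integer(sim$nSnv))
}

setMethod("show", "SimReplicate", function(object) {
  cat(sprintf("SimReplicate: %d / %d sites are SNVs (%.2f%%)\n",
              object@nSnv, object@nSitesTotal,
              100 * object@nSnv / object@nSitesTotal))
  invisible(object)
})

#' Tail probability of the ancestral frequency distribution
#'
#' Probability that a beta-distributed ancestral frequency falls outside
#' the open interval `(lo, hi)`, computed with the regularized incomplete
#' beta function.  For the default shapes `c(0.4, 0.4)` roughly 19% of
#' sites fall outside (0.01, 0.99) and 36% outside (0.05, 0.95).
#'
#' @param shape length-2 beta shape parameters.
#' @param bounds length-2 numeric `(lo, hi)`.
#' @return The tail probability.
#' @examples
#' ancestralTailCheck(c(0.4, 0.4), c(0.01, 0.99))
#' @export
ancestralTailCheck <- function(shape = c(0.4, 0.4), bounds) {
  stopifnot(length(shape) == 2, all(shape > 0), length(bounds) == 2)
  pbeta(bounds[1], shape[1], shape[2]) +
    pbeta(bounds[2], shape[1], shape[2], lower.tail = FALSE)
}

#' Monte-Carlo truth for mismatch-type FST under admixture
#'
#' With an admixture edge the tree formulas no longer apply, so the true
#' between-unit mismatch-type FST values are obtained by simulating
#' population frequencies only (no gamete sampling) at a large number of
#' sites and evaluating the mismatch-probability definition
#' `1 - (E[p_k(1-p_k)] + E[p_k'(1-p_k')]) / (E[p_k(1-p_k')] +
#' E[p_k'(1-p_k)])` with site averages.  Standard errors are estimated by
#' batching the sites.
#'
#' @param config a [ScenarioConfig-class] with `alpha` set.
#' @param nOracleSites number of frequency-level sites (default 1e6).
#' @param seed optional integer seed.
#' @param nBatches number of batches for the standard errors.
#' @return `list(H = K x K truth matrix, se = K x K standard errors)`.
#' @export
admixtureTruth <- function(config, nOracleSites = 1e6, seed = NULL,
                           nBatches = 100L) {
  if (is.na(config@alpha))
    stop("admixtureTruth requires a config with alpha set")
  if (!is.null(seed)) set.seed(seed)
  tree <- config@tree
  tips <- .tipNodes(tree)
  tl <- tree@labels[tips]
  K <- length(tips)
  freqs <- .simFreqs(config, nSites = as.integer(nOracleSites))[, tips,
                                                               drop = FALSE]
  hFrom <- function(P) {
    het <- colMeans(P * (1 - P))
    C <- crossprod(P) / nrow(P)
    pbar <- colMeans(P)
    mis <- outer(pbar, pbar, "+") - 2 * C
    H <- 1 - outer(het, het, "+") / mis
    diag(H) <- 0
    H
  }
  H <- hFrom(freqs)
  dimnames(H) <- list(tl, tl)
  batch <- rep(seq_len(nBatches), length.out = nrow(freqs))
  Hb <- vapply(seq_len(nBatches),
               function(b) hFrom(freqs[batch == b, , drop = FALSE]),
               matrix(0, K, K))
  se <- apply(Hb, c(1, 2), sd) / sqrt(nBatches)
  dimnames(se) <- list(tl, tl)
  list(H = H, se = se)
}
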