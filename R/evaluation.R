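# Benchmarking of the estimators on simulated scenarios: per-pair RMSE of
# the tree-based and pairwise mismatch-type FST estimators, RMSE ratios,
# topology recovery rate, and estimate-truth correlations.

.cladeSet <- function(tree) {
  parent <- tree@parent
  tips <- .tipNodes(tree)
  below <- lapply(seq_along(parent), function(i) character(0))
  for (t in tips) {
    node <- t
    repeat {
      below[[node]] <- c(below[[node]], tree@labels[t])
      if (parent[node] == 0L) break
      node <- parent[node]
    }
  }
  internal <- setdiff(seq_along(parent), tips)
  sort(vapply(internal,
              function(i) paste(sort(below[[i]]), collapse = "|"),
              character(1)))
}

#' Compare two rooted topologies
#'
#' Two rooted trees are topologically equal when their sets of clades (tip
#' subsets below each internal node) coincide; branch parameters and child
#' order are ignored.
#'
#' @param t1,t2 [PopulationTree-class] objects over the same tip labels.
#' @return `TRUE` or `FALSE`.
#' @export
topologyEqual <- function(t1, t2) {
  if (!setequal(tipLabels(t1), tipLabels(t2)))
    stop("trees must share the same tip label set")
  identical(.cladeSet(t1), .cladeSet(t2))
}

#' Run a simulation scenario and score the estimators
#'
#' For each replicate: simulate counts, compute the pairwise ratio-of-sums
#' estimator and the jointly inferred tree (clustering plus improvement
#' phases), evaluate the tree-based FST matrices, and score everything
#' against the exact model truths (tree formulas, or the frequency-level
#' Monte-Carlo oracle when the scenario includes admixture).  Replicates
#' with an undefined required estimate are excluded and tallied.
#'
#' @param config a [ScenarioConfig-class].
#' @param nReps number of simulation replicates.
#' @param seed integer seed; the report is deterministic given
#'   `(config, nReps, seed)`.
#' @param passesCap,clipEps forwarded to the tree inference.
#' @param nOracleSites frequency-level sites for the admixture truth
#'   oracle (ignored without admixture).
#' @return An [EvaluationReport-class] object.
#' @export
runScenario <- function(config, nReps, seed = 1L, passesCap = 10L,
                        clipEps = 1e-12, nOracleSites = 1e6) {
  set.seed(seed)
  tree <- config@tree
  tl <- tipLabels(tree)
  K <- length(tl)
  admixed <- !is.na(config@alpha)
  if (admixed) {
    trueH <- admixtureTruth(config, nOracleSites = nOracleSites)$H
    trueW <- matrix(NA_real_, K, K, dimnames = list(tl, tl))
  } else {
    tru <- coancestryMatrices(tree)
    trueH <- tru@H[tl, tl]
    trueW <- tru@W[tl, tl]
  }
  up <- upper.tri(trueH)
  seHt <- seHp <- seWt <- matrix(0, K, K, dimnames = list(tl, tl))
  nTopo <- 0L
  nUsed <- 0L
  nExcluded <- 0L
  sumCorT <- sumCorP <- 0
  trueClades <- .cladeSet(tree)

  for (rep in seq_len(nReps)) {
    sim <- .simCountsCore(config)
    cs <- .pairSumsCore(sim$ref, sim$n)
    off <- !diag(K)
    if (any(cs$sumD[off] == 0)) {
      nExcluded <- nExcluded + 1L
      next
    }
    Fp <- cs$sumNH / cs$sumD
    S <- 2 * cs$sumN / cs$sumD
    S[!off] <- NA_real_
    core <- .inferFromS(S, passesCap = passesCap, clipEps = clipEps)
    fitTree <- .asPopulationTree(core)
    est <- coancestryMatrices(fitTree)
    Ht <- est@H[tl, tl]
    Wt <- est@W[tl, tl]
    seHt <- seHt + (Ht - trueH)^2
    seHp <- seHp + (Fp - trueH)^2
    if (!admixed) seWt <- seWt + (Wt - trueW)^2
    if (identical(.cladeSet(fitTree), trueClades)) nTopo <- nTopo + 1L
    sumCorT <- sumCorT + cor(Ht[up], trueH[up])
    sumCorP <- sumCorP + cor(Fp[up], trueH[up])
    nUsed <- nUsed + 1L
  }
  if (nUsed == 0L) stop("no usable replicates")
  rmseHt <- sqrt(seHt / nUsed)
  rmseHp <- sqrt(seHp / nUsed)
  rmseWt <- if (admixed) trueW * NA_real_ else sqrt(seWt / nUsed)
  diag(rmseHt) <- diag(rmseHp) <- 0
  ratio <- rmseHp / rmseHt
  diag(ratio) <- NA_real_
  new("EvaluationReport", config = config,
      truth = new("CoancestryEstimates", labels = tl,
                  W = if (admixed) matrix(0, K, K, dimnames = list(tl, tl))
                      else trueW,
                  H = trueH),
      rmseHtree = rmseHt, rmseHpair = rmseHp, rmseWtree = rmseWt,
      rmseRatio = ratio, meanRmseRatio = mean(ratio[up]),
      topologyRate = nTopo / nUsed,
      corTreeMean = sumCorT / nUsed, corPairMean = sumCorP / nUsed,
      nReps = as.integer(nUsed), nExcluded = as.integer(nExcluded),
      seed = as.integer(seed))
}

#' Per-pair summary table of an evaluation report
#'
#' One row per unordered unit pair: the true mismatch-type FST, the RMSEs
#' (scaled by 1e4) of the tree-based and pairwise estimators, and their
#' ratio.
#'
#' @param report an [EvaluationReport-class].
#' @return A data frame.
#' @export
reportTable <- function(report) {
  tl <- report@truth@labels
  K <- length(tl)
  idx <- which(upper.tri(report@rmseHtree), arr.ind = TRUE)
  data.frame(
    pair = paste0(tl[idx[, 1]], tl[idx[, 2]]),
    trueFSTH = report@truth@H[idx],
    rmseTree1e4 = 1e4 * report@rmseHtree[idx],
    rmsePairwise1e4 = 1e4 * report@rmseHpair[idx],
    rmseRatio = report@rmseRatio[idx],
    stringsAsFactors = FALSE)
}

#' Write an evaluation report as JSON
#'
#' @param report an [EvaluationReport-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeReportJson <- function(report, path) {
  obj <- list(
    scenario = report@config@name,
    seed = report@seed,
    nReps = report@nReps,
    nExcluded = report@nExcluded,
    topologyRate = report@topologyRate,
    meanRmseRatio = report@meanRmseRatio,
    corTreeMean = report@corTreeMean,
    corPairMean = report@corPairMean,
    pairs = reportTable(report))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

setMethod("show", "EvaluationReport", function(object) {
  cat(sprintf("EvaluationReport: scenario '%s', %d replicates (%d excluded)\n",
              object@config@name, object@nReps, object@nExcluded))
  cat(sprintf("topology recovery: %.2f%%\n", 100 * object@topologyRate))
  cat(sprintf("mean RMSE ratio (pairwise / tree): %.3f\n",
              object@meanRmseRatio))
  cat(sprintf("mean estimate-truth correlation: tree %.4f, pairwise %.4f\n",
              object@corTreeMean, object@corPairMean))
  print(reportTable(object), digits = 3)
  invisible(object)
})
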