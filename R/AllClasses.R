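# Central S4 classes.  AlleleCounts wraps a SummarizedExperiment carrying two
# integer assays: "ref" (copies of the counted allele) and "n" (gametes
# sampled).  A missing cell is NA in both assays.

#' AlleleCounts: per-locus allele counts for K units
#'
#' An `AlleleCounts` object holds, for each of m loci (rows) and K units
#' (columns), the number of copies of the counted allele (`ref` assay) and
#' the number of gametes sampled (`n` assay).  A unit is either a population
#' sample or a diploid individual treated as a population of two gametes.
#' Missing cells are `NA` in both assays; all downstream pairwise statistics
#' are computed over loci observed in both members of the pair.
#'
#' All statistics in the package use `p*(1-p)`-type forms and are therefore
#' invariant to which of the two alleles is counted.
#'
#' @slot .  Inherits from [SummarizedExperiment::SummarizedExperiment] with
#'   assays `ref` and `n`.
#'
#' @seealso [alleleCounts()], [readCountsTable()], [diploidsToUnits()],
#'   [poolUnits()]
#' @export
setClass("AlleleCounts", contains = "SummarizedExperiment")

setValidity("AlleleCounts", function(object) {
  an <- assayNames(object)
  if (!all(c("ref", "n") %in% an))
    return("assays 'ref' and 'n' are required")
  ref <- assay(object, "ref")
  n <- assay(object, "n")
  if (ncol(ref) < 2L)
    return("at least K = 2 units are required")
  if (is.null(colnames(ref)) || anyDuplicated(colnames(ref)))
    return("unit labels must be present and unique")
  if (is.null(rownames(ref)) || anyDuplicated(rownames(ref)))
    return("locus identifiers must be present and unique")
  if (!identical(is.na(ref), is.na(n)))
    return("missingness of 'ref' and 'n' must agree cell by cell")
  ok <- !is.na(ref)
  if (any(ref[ok] < 0L))
    return("negative allele counts are not allowed")
  if (any(ref[ok] > n[ok]))
    return("allele count exceeds gametes sampled at some cell")
  if (any(n[ok] < 2L))
    return("every non-missing cell needs at least 2 gametes")
  TRUE
})

#' PopulationTree: rooted tree with branch drift parameters
#'
#' Nodes are stored as a parent-pointer vector; the single node with parent
#' 0 is the root (the global ancestral population).  Every non-root node q
#' carries a drift parameter `theta[q]` in `[0, 1]` for the branch above it;
#' the label of a node also names that branch.  Tips carry the unit labels.
#' Zero-length branches are allowed, so non-binary structures can be
#' represented inside a binary tree.
#'
#' @slot parent integer vector; `parent[i]` is the node index of the parent
#'   of node i, 0 for the root.
#' @slot labels character vector of node labels; tip labels must be unique.
#' @slot theta numeric vector of branch parameters in `[0, 1]`; `NA` at the
#'   root.
#'
#' @seealso [populationTree()], [starTree()], [scenarioTree()],
#'   [coancestryMatrices()]
#' @export
setClass("PopulationTree",
  representation(parent = "integer", labels = "character", theta = "numeric"))

setValidity("PopulationTree", function(object) {
  p <- object@parent
  N <- length(p)
  if (length(object@labels) != N || length(object@theta) != N)
    return("parent, labels and theta must have one entry per node")
  root <- which(p == 0L)
  if (length(root) != 1L)
    return("exactly one root (parent 0) is required")
  if (any(p < 0L) || any(p > N))
    return("parent indices out of range")
  # acyclic & connected: every node must reach the root
  for (i in seq_len(N)) {
    j <- i; steps <- 0L
    while (p[j] != 0L) {
      j <- p[j]; steps <- steps + 1L
      if (steps > N) return("cycle detected in parent pointers")
    }
  }
  tips <- setdiff(seq_len(N), p)
  if (anyDuplicated(object@labels[tips]))
    return("tip labels must be unique")
  th <- object@theta[-root]
  if (anyNA(th) || any(th < 0) || any(th > 1))
    return("theta must lie in [0, 1] on every non-root branch")
  if (!is.na(object@theta[root]))
    return("the root carries no theta (must be NA)")
  TRUE
})

#' PairSummaries: per-pair moment sums and the S statistic
#'
#' For every ordered pair of units (k, k') the object stores the locus sums
#' entering the pairwise and tree-based moment estimators, taken over loci
#' non-missing in both members of the pair:
#' * `sumN[k, k']`: sum of `n_k/(n_k-1) * p_k(1-p_k)` (within-unit
#'   heterozygosity of the first member, small-sample corrected per locus);
#' * `sumD[k, k']`: sum of the mismatch term `p_k(1-p_k') + p_k'(1-p_k)`
#'   (symmetric);
#' * `sumNH[k, k']`: sum of the pairwise-estimator numerator (symmetric);
#' * `S[k, k'] = 2 * sumN[k, k'] / sumD[k, k']`, the raw (unclipped)
#'   scaled-heterozygosity statistic whose expectation is the product of
#'   `(1 - theta)` over branches ancestral to k but not to k'.
#'
#' `S` is asymmetric; it is undefined (and `sDefined` is `FALSE`) for pairs
#' with `sumD == 0`, i.e. when both units are fixed at every shared locus.
#'
#' @seealso [pairSums()], [sMatrix()], [hudsonPairwise()]
#' @export
setClass("PairSummaries",
  representation(labels = "character", sumN = "matrix", sumD = "matrix",
                 sumNH = "matrix", nLoci = "matrix", S = "matrix",
                 sDefined = "matrix"))

setValidity("PairSummaries", function(object) {
  K <- length(object@labels)
  for (nm in c("sumN", "sumD", "sumNH", "nLoci", "S", "sDefined")) {
    m <- slot(object, nm)
    if (!all(dim(m) == c(K, K))) return(sprintf("%s must be K x K", nm))
  }
  off <- !diag(K)
  if (any(object@sumD[off] < 0)) return("sumD must be non-negative")
  if (!isTRUE(all.equal(object@sumD, t(object@sumD))))
    return("sumD must be symmetric")
  if (any(object@sDefined[off] != (object@sumD[off] > 0)))
    return("sDefined must flag exactly the pairs with sumD > 0")
  TRUE
})

#' CoancestryEstimates: generalized FST matrices from a tree
#'
#' `W` is the matrix of shared-variance (correlation-type) FST values:
#' `W[k, k']` depends on the branches shared by the root-to-tip paths of k
#' and k', and the diagonal `W[k, k]` measures the divergence of unit k from
#' the root.  `H` is the matrix of mismatch-type (Hudson-type) FST values,
#' driven by the non-shared branches, with a structurally zero diagonal.
#'
#' @seealso [coancestryMatrices()], [fstW()], [fstH()]
#' @export
setClass("CoancestryEstimates",
  representation(labels = "character", W = "matrix", H = "matrix"))

setValidity("CoancestryEstimates", function(object) {
  K <- length(object@labels)
  if (!all(dim(object@W) == c(K, K)) || !all(dim(object@H) == c(K, K)))
    return("W and H must be K x K")
  if (!isTRUE(all.equal(object@W, t(object@W))) ||
      !isTRUE(all.equal(object@H, t(object@H))))
    return("W and H must be symmetric")
  if (any(diag(object@H) != 0)) return("diagonal of H must be exactly 0")
  v <- c(object@W, object@H)
  if (any(v < -1e-12 | v > 1 + 1e-12)) return("entries must lie in [0, 1]")
  TRUE
})

#' ScenarioConfig: settings for the beta-drift simulator
#'
#' Bundles a theta-labelled tree, the number of gametes sampled per unit,
#' the number of sites to simulate, the shape parameters of the ancestral
#' allele-frequency beta distribution, and an optional admixture fraction
#' `alpha` by which the parent node of `admixTip` draws its frequency from
#' `admixSource` instead of its own parent.
#'
#' @seealso [scenarioConfig()], [simulateReplicate()]
#' @export
setClass("ScenarioConfig",
  representation(tree = "PopulationTree", gametes = "integer",
                 nSites = "integer", shape = "numeric", alpha = "numeric",
                 admixTip = "character", admixSource = "character",
                 name = "character"))

setValidity("ScenarioConfig", function(object) {
  K <- length(tipLabels(object@tree))
  if (length(object@gametes) != K) return("one gamete count per unit needed")
  if (any(object@gametes < 2L)) return("at least 2 gametes per unit")
  if (object@nSites < 1L) return("nSites must be >= 1")
  if (length(object@shape) != 2L || any(object@shape <= 0))
    return("shape must be two positive numbers")
  a <- object@alpha
  if (!is.na(a) && (a < 0 || a > 1)) return("alpha must lie in [0, 1]")
  TRUE
})

#' SimReplicate: one simulated allele-count dataset
#'
#' Holds the sampled counts (restricted to sites that are SNVs, i.e. carry
#' at least one copy of a minor allele in the pooled sample), the true
#' per-node allele frequencies at the retained sites, and site bookkeeping.
#'
#' @seealso [simulateReplicate()]
#' @export
setClass("SimReplicate",
  representation(counts = "AlleleCounts", nodeFreqs = "matrix",
                 nSitesTotal = "integer", nSnv = "integer"))

#' FitResult: fitted tree and objective value
#'
#' The tree carries the estimated branch parameters `theta = 1 - exp(beta)`
#' where `beta <= 0` minimizes the logarithmic least-squares objective `xi`
#' (residual sum of squares of `log S` against the branch sums).
#'
#' @seealso [fitThetas()], [inferTree()]
#' @export
setClass("FitResult",
  representation(tree = "PopulationTree", xi = "numeric",
                 rowsUsed = "integer", diagnostics = "list"))

setValidity("FitResult", function(object) {
  if (object@xi < 0) return("xi must be non-negative")
  TRUE
})

#' EvaluationReport: estimator performance over simulation replicates
#'
#' Per-pair root-mean-square errors of the tree-based and pairwise
#' mismatch-type FST estimators (and of the tree-based shared-variance
#' estimator) against the exact model truths, RMSE ratios, the fraction of
#' replicates with correctly inferred topology, and mean per-replicate
#' estimate-truth correlations.
#'
#' @seealso [runScenario()]
#' @export
setClass("EvaluationReport",
  representation(config = "ScenarioConfig", truth = "CoancestryEstimates",
                 rmseHtree = "matrix", rmseHpair = "matrix",
                 rmseWtree = "matrix", rmseRatio = "matrix",
                 meanRmseRatio = "numeric", topologyRate = "numeric",
                 corTreeMean = "numeric", corPairMean = "numeric",
                 nReps = "integer", nExcluded = "integer", seed = "integer"))
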