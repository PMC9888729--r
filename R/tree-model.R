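# Rooted population trees with branch drift parameters, the path-set
# algebra on them, and the generalized FST definitions computed from a
# parameterized tree.
#
# Convention: the label of a node also names the branch above it, so branch
# sets are reported as node labels.  Products of (1 - theta) are computed
# as exp(sum(log1p(-theta))) for stability, with theta = 1 giving an exact
# zero factor.

#' Construct a PopulationTree
#'
#' @param parent integer vector, `parent[i]` the node index of node i's
#'   parent, 0 for the (single) root.
#' @param labels character node labels; tips (childless nodes) must be
#'   uniquely labelled.
#' @param theta numeric branch parameters in `[0, 1]`, one per node, `NA`
#'   at the root.
#' @return A validated [PopulationTree-class].
#' @examples
#' # root with two tips
#' populationTree(parent = c(0L, 1L, 1L), labels = c("0", "A", "B"),
#'                theta = c(NA, 0.1, 0.2))
#' @export
populationTree <- function(parent, labels, theta) {
  new("PopulationTree", parent = as.integer(parent),
      labels = as.character(labels), theta = as.numeric(theta))
}

#' Star tree: every unit a direct child of the root
#'
#' The independent-descent model: all units diverge directly from the
#' common ancestral population.
#'
#' @param labels tip labels.
#' @param theta branch parameters for the tips (recycled; default 0).
#' @param rootLabel label of the root node.
#' @return A [PopulationTree-class].
#' @export
starTree <- function(labels, theta = 0, rootLabel = "0") {
  K <- length(labels)
  populationTree(parent = c(0L, rep(1L, K)),
                 labels = c(rootLabel, labels),
                 theta = c(NA, rep_len(theta, K)))
}

#' The five-population reference tree of the bundled scenarios
#'
#' Tips A and B share ancestral population 1; tips C and D share ancestral
#' population 3, which together with tip E descends from ancestral
#' population 2.  Branch parameters: 0.15 above populations 1 and 2, 0.10
#' above D, and 0.05 elsewhere.  This tree defines the truth for all
#' bundled simulation scenarios.
#'
#' @return A [PopulationTree-class] with 5 tips.
#' @export
scenarioTree <- function() {
  populationTree(
    parent = c(0L, 1L, 1L, 3L, 2L, 2L, 4L, 4L, 3L),
    labels = c("0", "1", "2", "3", "A", "B", "C", "D", "E"),
    theta = c(NA, 0.15, 0.15, 0.05, 0.05, 0.05, 0.05, 0.10, 0.05))
}

.rootNode <- function(tree) which(tree@parent == 0L)

.tipNodes <- function(tree) setdiff(seq_along(tree@parent), tree@parent)

#' @describeIn populationTree tip labels, in node-index order.
#' @export
setMethod("tipLabels", "PopulationTree",
          function(x) x@labels[.tipNodes(x)])

#' @describeIn populationTree named branch parameters (non-root nodes).
#' @export
setMethod("thetas", "PopulationTree", function(x) {
  nr <- which(x@parent != 0L)
  setNames(x@theta[nr], x@labels[nr])
})

setMethod("show", "PopulationTree", function(object) {
  K <- length(.tipNodes(object))
  cat(sprintf("PopulationTree: %d tips, %d nodes\n",
              K, length(object@parent)))
  cat(writeNewick(object), "\n")
  invisible(object)
})

.nodeIndex <- function(tree, label) {
  i <- match(label, tree@labels)
  if (is.na(i)) stop("unknown node label: ", label)
  i
}

# node indices on the path root -> node, excluding the root (i.e. the
# branches above each visited node), ordered tipward-to-rootward.
.pathNodes <- function(tree, node) {
  out <- integer(0)
  while (tree@parent[node] != 0L) {
    out <- c(out, node)
    node <- tree@parent[node]
  }
  out
}

#' Shared and non-shared branch sets for a pair of tips
#'
#' For tips k and k', returns the most recent common ancestor M, the set Q
#' of branches shared by the two root-to-tip paths (those between the root
#' and M), and the set R of branches on k's path but not on k's partner's
#' (those between M and k).  Branches are named by the node below them.
#'
#' @param tree a [PopulationTree-class].
#' @param k,kp tip labels.  `k == kp` is allowed: then `R` is empty and `Q`
#'   is the full path.
#' @return `list(M = <label>, Q = <labels>, R = <labels>)` where `R` is the
#'   branch set ancestral to `k` but not `kp` (note the asymmetry: swap the
#'   arguments for the reverse set).
#' @export
branchSets <- function(tree, k, kp) {
  ki <- .nodeIndex(tree, k)
  kpi <- .nodeIndex(tree, kp)
  pk <- .pathNodes(tree, ki)
  pkp <- .pathNodes(tree, kpi)
  Q <- intersect(pk, pkp)
  R <- setdiff(pk, pkp)
  M <- if (length(Q) > 0) {
    # deepest shared node: the first element of the shared path segment
    tree@labels[pk[match(TRUE, pk %in% Q)]]
  } else tree@labels[.rootNode(tree)]
  list(M = M, Q = tree@labels[Q], R = tree@labels[R])
}

.prodOneMinus <- function(theta) {
  if (length(theta) == 0) return(1)
  if (any(theta >= 1)) return(0)
  exp(sum(log1p(-theta)))
}

#' Shared-variance (correlation-type) FST between two tips
#'
#' `1 - prod(1 - theta)` over the branches shared by the root-to-tip paths
#' of `k` and `kp`.  With `kp = k` this is the divergence of the single
#' unit from the root; for tips whose paths share no branch it is zero.
#'
#' @param tree a [PopulationTree-class].
#' @param k,kp tip labels (`kp` defaults to `k`).
#' @return A value in `[0, 1]`.
#' @export
fstW <- function(tree, k, kp = k) {
  bs <- branchSets(tree, k, kp)
  1 - .prodOneMinus(tree@theta[match(bs$Q, tree@labels)])
}

#' Mismatch-type (Hudson-type) FST between two tips
#'
#' `1 - 0.5 * (prod over R(k,kp) + prod over R(kp,k))` of `(1 - theta)`,
#' where the R sets collect the branches ancestral to one tip but not the
#' other.  Zero when `k == kp`.
#'
#' @inheritParams fstW
#' @return A value in `[0, 1]`.
#' @export
fstH <- function(tree, k, kp) {
  b1 <- branchSets(tree, k, kp)
  b2 <- branchSets(tree, kp, k)
  1 - 0.5 * (.prodOneMinus(tree@theta[match(b1$R, tree@labels)]) +
             .prodOneMinus(tree@theta[match(b2$R, tree@labels)]))
}

#' Model expectation of the S statistic for an ordered tip pair
#'
#' `prod(1 - theta)` over the branches ancestral to `k` but not to `kp`.
#' Asymmetric in its arguments.
#'
#' @inheritParams fstW
#' @return A value in `(0, 1]`.
#' @export
expectedS <- function(tree, k, kp) {
  if (identical(k, kp)) stop("expectedS needs two distinct tips")
  bs <- branchSets(tree, k, kp)
  .prodOneMinus(tree@theta[match(bs$R, tree@labels)])
}

#' Coancestry matrices from a parameterized tree
#'
#' Evaluates the shared-variance matrix `W` (including single-unit
#' divergences on the diagonal) and the mismatch-type matrix `H` (zero
#' diagonal) for all tip pairs of the tree.
#'
#' @param tree a [PopulationTree-class] with branch parameters set.
#' @return A [CoancestryEstimates-class] object.
#' @examples
#' est <- coancestryMatrices(scenarioTree())
#' coancestryH(est)["C", "D"]   # 0.075
#' coancestryW(est)["D", "D"]   # 0.27325
#' @export
coancestryMatrices <- function(tree) {
  tl <- tipLabels(tree)
  K <- length(tl)
  W <- matrix(0, K, K, dimnames = list(tl, tl))
  H <- W
  for (i in seq_len(K)) {
    W[i, i] <- fstW(tree, tl[i])
    if (i < K) for (j in (i + 1):K) {
      W[i, j] <- W[j, i] <- fstW(tree, tl[i], tl[j])
      H[i, j] <- H[j, i] <- fstH(tree, tl[i], tl[j])
    }
  }
  new("CoancestryEstimates", labels = tl, W = W, H = H)
}

#' @describeIn coancestryMatrices shared-variance FST matrix.
#' @export
setMethod("coancestryW", "CoancestryEstimates", function(x) x@W)

#' @describeIn coancestryMatrices mismatch-type FST matrix.
#' @export
setMethod("coancestryH", "CoancestryEstimates", function(x) x@H)

setMethod("show", "CoancestryEstimates", function(object) {
  cat("CoancestryEstimates\nW (shared variance):\n")
  print(round(object@W, 4))
  cat("H (mismatch):\n")
  print(round(object@H, 4))
  invisible(object)
})

## ---- newick serialization ------------------------------------------------

.quoteNewickLabel <- function(x) {
  needs <- grepl("[][ \t(){}:;,']", x)
  x[needs] <- paste0("'", gsub("'", "''", x[needs]), "'")
  x
}

#' Serialize a PopulationTree to a newick string
#'
#' Branch lengths carry the theta parameters; internal nodes keep their
#' labels.  Labels containing whitespace or newick metacharacters are
#' single-quoted.
#'
#' @param tree a [PopulationTree-class].
#' @param file optional path; when given the string is written there.
#' @return The newick string (invisibly when `file` is given).
#' @seealso [readNewick()]
#' @export
writeNewick <- function(tree, file = NULL) {
  kids <- split(seq_along(tree@parent), tree@parent)
  lab <- .quoteNewickLabel(tree@labels)
  rec <- function(node) {
    ch <- kids[[as.character(node)]]
    core <- if (is.null(ch)) lab[node] else
      paste0("(", paste(vapply(ch, rec, character(1)), collapse = ","), ")",
             lab[node])
    if (tree@parent[node] == 0L) core
    else paste0(core, ":", format(tree@theta[node], digits = 15))
  }
  s <- paste0(rec(.rootNode(tree)), ";")
  if (!is.null(file)) {
    writeLines(s, file)
    return(invisible(s))
  }
  s
}

#' Read a PopulationTree from a newick string or file
#'
#' Branch lengths are interpreted as theta parameters and must lie in
#' `[0, 1]`; every branch must carry one.  Internal node labels are kept
#' (or auto-generated when absent).
#'
#' @param text newick string, or `NULL` to read from `file`.
#' @param file path to a newick file.
#' @return A [PopulationTree-class].
#' @export
readNewick <- function(text = NULL, file = NULL) {
  if (is.null(text)) text <- paste(readLines(file, warn = FALSE),
                                   collapse = "")
  # mask quoted labels with plain placeholders so the parser cannot split
  # them on metacharacters, then restore after parsing
  quoted <- regmatches(text, gregexpr("'(?:[^']|'')*'", text))[[1]]
  restored <- gsub("''", "'", substr(quoted, 2, nchar(quoted) - 1))
  for (i in seq_along(quoted)) {
    text <- sub(quoted[i], sprintf("QLBL%dQ", i), text, fixed = TRUE)
  }
  phy <- ape::read.tree(text = text)
  if (is.null(phy)) stop("malformed newick input")
  unmask <- function(x) {
    m <- regmatches(x, regexec("^QLBL([0-9]+)Q$", x))
    for (j in seq_along(x))
      if (length(m[[j]]) == 2) x[j] <- restored[as.integer(m[[j]][2])]
    x
  }
  phy$tip.label <- unmask(phy$tip.label)
  if (!is.null(phy$node.label)) phy$node.label <- unmask(phy$node.label)
  phyloToTree(phy)
}

#' Convert a PopulationTree to an ape phylo object
#'
#' @param tree a [PopulationTree-class].
#' @return An object of class `phylo` with `edge.length` set to theta and
#'   internal labels in `node.label`.
#' @export
treeToPhylo <- function(tree) {
  tips <- .tipNodes(tree)
  internals <- c(.rootNode(tree),
                 setdiff(which(tree@parent != 0L), tips))
  idx <- integer(length(tree@parent))
  idx[tips] <- seq_along(tips)
  idx[internals] <- length(tips) + seq_along(internals)
  nonroot <- which(tree@parent != 0L)
  phy <- structure(list(
    edge = cbind(idx[tree@parent[nonroot]], idx[nonroot]),
    edge.length = tree@theta[nonroot],
    tip.label = tree@labels[tips],
    node.label = tree@labels[internals],
    Nnode = length(internals)), class = "phylo", order = "cladewise")
  ape::reorder.phylo(phy)
}

#' Convert an ape phylo object to a PopulationTree
#'
#' @param phy a rooted `phylo` object whose `edge.length` values (all
#'   required, in `[0, 1]`) are taken as theta parameters.
#' @return A [PopulationTree-class].
#' @export
phyloToTree <- function(phy) {
  if (is.null(phy$edge.length))
    stop("branch lengths (theta) are required")
  if (any(is.na(phy$edge.length)) || any(phy$edge.length < 0) ||
      any(phy$edge.length > 1))
    stop("theta branch lengths must lie in [0, 1]")
  K <- length(phy$tip.label)
  N <- K + phy$Nnode
  parent <- integer(N)
  theta <- rep(NA_real_, N)
  parent[phy$edge[, 2]] <- phy$edge[, 1]
  theta[phy$edge[, 2]] <- phy$edge.length
  stripQ <- function(x) {
    q <- grepl("^'.*'$", x)
    x[q] <- gsub("''", "'", substr(x[q], 2, nchar(x[q]) - 1))
    x
  }
  labels <- character(N)
  labels[seq_len(K)] <- stripQ(phy$tip.label)
  nl <- phy$node.label
  if (is.null(nl) || length(nl) != phy$Nnode || any(nl == ""))
    nl <- paste0("n", seq_len(phy$Nnode))
  labels[K + seq_len(phy$Nnode)] <- stripQ(nl)
  populationTree(parent, labels, theta)
}

#' @exportS3Method ape::as.phylo
as.phylo.PopulationTree <- function(x, ...) treeToPhylo(x)
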