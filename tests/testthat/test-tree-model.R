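test_that("branch sets follow the path algebra of the reference topology", {
  tr <- scenarioTree()
  ce <- branchSets(tr, "C", "E")
  expect_identical(ce$M, "2")
  expect_setequal(ce$Q, "2")
  expect_setequal(ce$R, c("3", "C"))
  expect_setequal(branchSets(tr, "E", "C")$R, "E")
  # same-tip call: R empty, Q the full path
  cc <- branchSets(tr, "C", "C")
  expect_length(cc$R, 0)
  expect_setequal(cc$Q, c("2", "3", "C"))
  # tips in different root subtrees share nothing
  ab <- branchSets(tr, "A", "E")
  expect_setequal(ab$Q, character(0))
  expect_identical(ab$M, "0")
  expect_error(branchSets(tr, "Z", "A"), "unknown node")
})

test_that("tree FST formulas reproduce the reference-tree truth table", {
  tr <- scenarioTree()
  expect_equal(fstW(tr, "A", "B"), 0.15)
  expect_equal(fstW(tr, "D"), 1 - 0.85 * 0.95 * 0.90)   # 0.27325
  expect_equal(fstW(tr, "A", "E"), 0)                   # disjoint paths
  expect_equal(fstH(tr, "C", "D"), 0.075)
  expect_equal(fstH(tr, "C", "E"), 1 - 0.5 * (0.95^2 + 0.95))  # 0.07375
  expect_equal(fstH(tr, "C", "C"), 0)
  expect_equal(expectedS(tr, "C", "E"), 0.9025)
  expect_equal(expectedS(tr, "E", "C"), 0.95)
  # star tree: mismatch FST is the average of the two thetas
  st <- starTree(c("x", "y"), theta = c(0.1, 0.3))
  expect_equal(fstH(st, "x", "y"), 0.2)
  expect_equal(expectedS(st, "x", "y"), 0.9)
})

test_that("coancestry matrices reproduce every distinct printed truth", {
  est <- coancestryMatrices(scenarioTree())
  H <- coancestryH(est)
  W <- coancestryW(est)
  # between-population mismatch truths (printed to 3 decimals)
  expect_equal(H["A", "B"], 0.050, tolerance = 1e-12)
  expect_equal(H["C", "E"], 0.07375, tolerance = 1e-12)
  expect_equal(H["C", "D"], 0.075, tolerance = 1e-12)
  expect_equal(H["D", "E"], 0.0975, tolerance = 1e-12)
  expect_equal(H["A", "E"], 0.1925, tolerance = 1e-12)
  expect_equal(H["B", "E"], 0.1925, tolerance = 1e-12)
  expect_equal(H["A", "C"], 0.2126875, tolerance = 1e-12)
  expect_equal(H["B", "C"], 0.2126875, tolerance = 1e-12)
  expect_equal(H["A", "D"], 0.232875, tolerance = 1e-12)
  expect_equal(H["B", "D"], 0.232875, tolerance = 1e-12)
  # shared-variance truths, including single-unit divergences
  expect_equal(W["A", "B"], 0.150, tolerance = 1e-12)
  expect_equal(W["C", "E"], 0.150, tolerance = 1e-12)
  expect_equal(W["D", "E"], 0.150, tolerance = 1e-12)
  expect_equal(W["A", "A"], 0.1925, tolerance = 1e-12)
  expect_equal(W["B", "B"], 0.1925, tolerance = 1e-12)
  expect_equal(W["E", "E"], 0.1925, tolerance = 1e-12)
  expect_equal(W["C", "D"], 0.1925, tolerance = 1e-12)
  expect_equal(W["C", "C"], 0.232875, tolerance = 1e-12)
  expect_equal(W["D", "D"], 0.27325, tolerance = 1e-12)
  expect_equal(diag(H), setNames(rep(0, 5), colnames(H)))
})

test_that("all-zero and star parameterizations degenerate correctly", {
  tr <- scenarioTree()
  tr0 <- populationTree(tr@parent, tr@labels,
                        ifelse(is.na(tr@theta), NA, 0))
  est0 <- coancestryMatrices(tr0)
  expect_true(all(coancestryW(est0) == 0) && all(coancestryH(est0) == 0))
  for (pair in list(c("A", "B"), c("C", "E")))
    expect_equal(expectedS(tr0, pair[1], pair[2]), 1)
  # independent-descent star: W diagonal = theta, off-diagonal 0
  st <- starTree(c("u", "v", "w"), theta = c(0.1, 0.2, 0.3))
  estS <- coancestryMatrices(st)
  expect_equal(diag(coancestryW(estS)), c(u = 0.1, v = 0.2, w = 0.3))
  expect_true(all(coancestryW(estS)[upper.tri(diag(3))] == 0))
})

test_that("zero-length branches never change FST values", {
  tr <- scenarioTree()
  # splice a theta = 0 node between node "3" and its parent "2"
  parent <- c(tr@parent, fstree:::.nodeIndex(tr, "2"))
  labels <- c(tr@labels, "z")
  theta <- c(tr@theta, 0)
  i3 <- fstree:::.nodeIndex(tr, "3")
  parent[i3] <- length(parent)
  tr2 <- populationTree(parent, labels, theta)
  expect_equal(coancestryW(coancestryMatrices(tr2)),
               coancestryW(coancestryMatrices(tr)))
  expect_equal(coancestryH(coancestryMatrices(tr2)),
               coancestryH(coancestryMatrices(tr)))
})

test_that("H depends only on non-shared branches and W only on shared ones", {
  tr <- scenarioTree()
  bump <- function(tree, label, value) {
    th <- tree@theta
    th[fstree:::.nodeIndex(tree, label)] <- value
    populationTree(tree@parent, tree@labels, th)
  }
  # branch "2" is shared for (C,E): H must not move, W must
  tr2 <- bump(tr, "2", 0.4)
  expect_equal(fstH(tr2, "C", "E"), fstH(tr, "C", "E"))
  expect_false(fstW(tr2, "C", "E") == fstW(tr, "C", "E"))
  # branch "C" is non-shared for (C,E): W must not move, H must
  tr3 <- bump(tr, "C", 0.4)
  expect_equal(fstW(tr3, "C", "E"), fstW(tr, "C", "E"))
  expect_false(fstH(tr3, "C", "E") == fstH(tr, "C", "E"))
  # full-path identity: single-unit W equals 1 - prod over the whole path
  for (tip in tipLabels(tr)) {
    path <- branchSets(tr, tip, tip)$Q
    expect_equal(fstW(tr, tip),
                 1 - prod(1 - tr@theta[match(path, tr@labels)]))
  }
})

test_that("theta = 1 branches are handled exactly", {
  st <- starTree(c("x", "y"), theta = c(1, 0.5))
  expect_equal(fstW(st, "x"), 1)
  expect_equal(expectedS(st, "x", "y"), 0)
})

test_that("newick serialization round-trips topology, labels and theta", {
  tr <- scenarioTree()
  s <- writeNewick(tr)
  tr2 <- readNewick(text = s)
  expect_true(topologyEqual(tr, tr2))
  th1 <- thetas(tr); th2 <- thetas(tr2)
  expect_equal(th1[order(names(th1))], th2[order(names(th2))])
  # tip labels with spaces survive via quoting
  sp <- starTree(c("pop one", "pop,two"), theta = c(0.1, 0.2))
  sp2 <- readNewick(text = writeNewick(sp))
  expect_setequal(tipLabels(sp2), c("pop one", "pop,two"))
  expect_equal(sort(unname(thetas(sp2))), c(0.1, 0.2))
  # malformed input and out-of-range branch lengths are rejected
  expect_error(readNewick(text = "(A:0.1,B:-0.2)r;"), "\\[0, 1\\]")
  expect_error(readNewick(text = "(A:0.1,B:2.0)r;"), "\\[0, 1\\]")
  expect_error(suppressWarnings(readNewick(text = "(A:0.1,B")))
})

test_that("phylo conversion preserves structure for ape interoperability", {
  tr <- scenarioTree()
  phy <- treeToPhylo(tr)
  expect_s3_class(phy, "phylo")
  expect_setequal(phy$tip.label, tipLabels(tr))
  back <- phyloToTree(phy)
  expect_true(topologyEqual(tr, back))
})

test_that("tree validity catches malformed structures", {
  expect_error(populationTree(c(0L, 0L, 1L), c("0", "1", "A"),
                              c(NA, 0.1, 0.1)), "exactly one root")
  expect_error(populationTree(c(2L, 1L), c("a", "b"), c(0.1, 0.1)),
               "root|cycle")
  expect_error(populationTree(c(0L, 1L, 1L), c("0", "A", "A"),
                              c(NA, 0.1, 0.1)), "unique")
  expect_error(populationTree(c(0L, 1L, 1L), c("0", "A", "B"),
                              c(NA, 1.2, 0.1)), "theta")
})
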