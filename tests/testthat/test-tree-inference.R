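test_that("design system has the expected structure", {
  # K = 3 star: 6 rows, 3 columns, one 1 per row in the first unit's column
  st <- starTree(c("a", "b", "c"), theta = 0.1)
  S <- noiselessS(st)
  ds <- designSystem(st, S)
  expect_equal(dim(ds$X), c(6L, 3L))
  expect_true(all(rowSums(ds$X) == 1))
  for (r in seq_len(nrow(ds$X)))
    expect_equal(unname(ds$X[r, ds$rows$k[r]]), 1)
  expect_true(all(ds$y >= 0))

  # reference topology: row (C, E) marks exactly branches {3, C}
  tr <- scenarioTree()
  ds2 <- designSystem(tr, noiselessS(tr))
  rce <- which(ds2$rows$k == "C" & ds2$rows$kp == "E")
  expect_setequal(colnames(ds2$X)[ds2$X[rce, ] == 1], c("3", "C"))
  # binary tree with K tips: K(K-1) rows, 2(K-1) columns
  expect_equal(dim(ds2$X), c(20L, 8L))
})

test_that("theta fitting recovers noiseless trees exactly", {
  tr <- scenarioTree()
  fit <- fitThetas(tr, noiselessS(tr))
  expect_lt(fit@xi, 1e-16)
  th <- thetas(fit@tree)
  tru <- thetas(tr)
  expect_equal(th[names(tru)], tru, tolerance = 1e-8)
})

test_that("K = 2 theta estimates follow the closed form 1 - S", {
  acm <- alleleCounts(ref = cbind(P1 = c(2L, 5L, 7L), P2 = c(6L, 1L, 8L)),
                      n = matrix(10L, 3, 2, dimnames = list(NULL, c("P1", "P2"))))
  ps <- pairSums(acm)
  S <- sMatrix(ps)
  res <- inferTree(acm, seed = 1)
  th <- thetas(res$fit@tree)
  expect_equal(unname(th["P1"]), 1 - S["P1", "P2"])
  expect_equal(unname(th["P2"]), 1 - S["P2", "P1"])
  # composition: the tree-based mismatch FST is the average of the thetas
  expect_equal(coancestryH(res$estimates)["P1", "P2"],
               (th[["P1"]] + th[["P2"]]) / 2)
})

test_that("NNLS solver agrees with reference implementations", {
  skip_if_not_installed("pracma")
  set.seed(21)
  for (i in 1:25) {
    m <- sample(4:20, 1); n <- sample(2:8, 1)
    X <- matrix(rbinom(m * n, 1, 0.5), m, n)
    y <- abs(rnorm(m))
    mine <- fstree:::.nnlsCpp(X, y)
    ref <- pracma::lsqnonneg(X, y)
    expect_equal(mine$gamma, ref$x, tolerance = 1e-8)
    expect_equal(mine$rss, ref$resid.norm, tolerance = 1e-8)
  }
})

test_that("NNLS matches a dense grid-search oracle on 3-branch systems", {
  set.seed(31)
  X <- matrix(c(1, 0, 0,
                0, 1, 0,
                0, 0, 1,
                1, 1, 0,
                1, 0, 1,
                0, 1, 1), 6, 3, byrow = TRUE)
  gTrue <- c(0.05, 0.08, 0.02)
  y <- as.vector(X %*% gTrue) + rnorm(6, sd = 0.005)
  sol <- fstree:::.nnlsCpp(X, y)
  # brute force over the grid gamma in [0, 0.15]^3, step 1e-3
  grid <- seq(0, 0.15, by = 1e-3)
  A <- crossprod(X); b <- crossprod(X, y); yy <- sum(y^2)
  G <- as.matrix(expand.grid(grid, grid, grid))
  rss <- yy - 2 * (G %*% b) + rowSums((G %*% A) * G)
  best <- G[which.min(rss), ]
  expect_lt(max(abs(sol$gamma - best)), 1.5e-3)   # within grid resolution
  expect_lte(sol$rss, min(rss) + 1e-12)
})

test_that("clustering phase recovers the reference topology from noiseless S
          and performs the expected number of merge fits", {
  tr <- scenarioTree()
  S <- noiselessS(tr)
  ct <- clusterPhase(S)
  expect_true(topologyEqual(ct, tr))
  # every internal node of the result has exactly two children
  tab <- table(ct@parent[ct@parent != 0])
  expect_true(all(tab == 2))
  # K = 2 is already binary: a star with both tips
  S2 <- S[c("A", "B"), c("A", "B")]
  ct2 <- clusterPhase(S2)
  expect_length(fstree:::.tipNodes(ct2), 2)
  # fit count across merge steps is sum_{j=3..K} choose(j, 2)
  rows <- fstree:::.rowsFromS(S)
  cl <- fstree:::.clusterCore(rows, colnames(S))
  expect_equal(cl$nFits, sum(choose(3:5, 2)))
})

test_that("the noiseless cluster+improve optimum matches exhaustive search", {
  skip_if_not_installed("phangorn")
  set.seed(41)
  for (K in c(4, 5)) {
    tr <- randomBinaryTree(LETTERS[1:K])
    S <- noiselessS(tr)
    set.seed(K)
    core <- fstree:::.inferFromS(S)
    oracle <- exhaustiveBestXi(S)
    expect_true(topologyEqual(fstree:::.asPopulationTree(core),
                              oracle$fit@tree))
    expect_true(topologyEqual(fstree:::.asPopulationTree(core), tr))
    expect_lt(core$xi, 1e-12)
    expect_lt(abs(core$xi - oracle$xi), 1e-10)
  }
})

test_that("noiseless identifiability holds for random trees up to 7 tips", {
  set.seed(51)
  for (K in c(3, 5, 6, 7)) {
    tr <- randomBinaryTree(paste0("t", 1:K))
    S <- noiselessS(tr)
    core <- fstree:::.inferFromS(S)
    fitTree <- fstree:::.asPopulationTree(core)
    expect_true(topologyEqual(fitTree, tr))
    th <- thetas(fitTree)
    tru <- thetas(tr)
    expect_equal(unname(th[tipLabels(tr)]), unname(tru[tipLabels(tr)]),
                 tolerance = 1e-6)
    expect_lt(core$xi, 1e-12)
  }
})

test_that("improvement phase repairs a deliberately mis-grafted tip", {
  tr <- scenarioTree()
  S <- noiselessS(tr)
  # swap tips D and E: same label set, wrong topology
  bad <- tr
  iD <- fstree:::.nodeIndex(tr, "D"); iE <- fstree:::.nodeIndex(tr, "E")
  lab <- bad@labels; lab[c(iD, iE)] <- lab[c(iE, iD)]
  bad <- populationTree(bad@parent, lab, bad@theta)
  expect_false(topologyEqual(bad, tr))
  xiBad <- fitThetas(bad, S)@xi
  expect_gt(xiBad, 1e-6)
  fixed <- improvePhase(bad, S, seed = 2)
  expect_true(topologyEqual(fixed, tr))
  expect_lt(fitThetas(fixed, S)@xi, 1e-12)
  # a tree already at the optimum is returned unchanged
  same <- improvePhase(tr, S, seed = 2)
  expect_true(topologyEqual(same, tr))
})

test_that("objective is non-increasing across accepted improvement moves", {
  set.seed(61)
  cfg <- scenarioConfig("S6")
  sim <- simulateReplicate(cfg, seed = 8)
  S <- sMatrix(pairSums(sim@counts))
  start <- clusterPhase(S)
  xi0 <- fitThetas(start, S)@xi
  better <- improvePhase(start, S, seed = 9)
  expect_lte(fitThetas(better, S)@xi, xi0 + 1e-12)
})

test_that("duplicated units collapse to sister tips with near-zero branches", {
  set.seed(71)
  cfg <- scenarioConfig("S4")
  sim <- fstree:::.simCountsCore(cfg)
  ref <- cbind(sim$ref, X = sim$ref[, "A"])
  n <- cbind(sim$n, X = sim$n[, "A"])
  rownames(ref) <- rownames(n) <- paste0("s", seq_len(nrow(ref)))
  acm <- alleleCounts(ref, n)
  res <- inferTree(acm, seed = 3)
  fitTree <- res$fit@tree
  iA <- fstree:::.nodeIndex(fitTree, "A")
  iX <- fstree:::.nodeIndex(fitTree, "X")
  expect_equal(fitTree@parent[iA], fitTree@parent[iX])  # sisters
  expect_lt(fitTree@theta[iA], 1e-6)
  expect_lt(fitTree@theta[iX], 1e-6)
})

test_that("inference is deterministic given the seed", {
  cfg <- scenarioConfig("S6")
  sim <- simulateReplicate(cfg, seed = 5)
  r1 <- inferTree(sim@counts, seed = 17)
  r2 <- inferTree(sim@counts, seed = 17)
  expect_identical(writeNewick(r1$fit@tree), writeNewick(r2$fit@tree))
  expect_identical(r1$fit@xi, r2$fit@xi)
  expect_identical(coancestryH(r1$estimates), coancestryH(r2$estimates))
})

test_that("under-determined systems fit with a warning rather than failing", {
  tr <- scenarioTree()
  S <- noiselessS(tr)
  S[upper.tri(S)] <- NA         # 10 ordered-pair rows remain (8 branches)
  S[2, 1] <- NA; S[3, 2] <- NA; S[4, 3] <- NA   # now 7 rows < 8 branches
  expect_warning(fitThetas(tr, S), "under-determined")
})
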