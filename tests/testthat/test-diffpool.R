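sage_params <- function(w_in, w_out, normalize = TRUE) {
  list(W = matrix(rnorm(2 * w_in * w_out), 2 * w_in, w_out),
       b = matrix(rnorm(w_out), 1), normalize = normalize)
}

test_that("SAGE layer matches the dense mean-aggregation oracle", {
  set.seed(31)
  # 4-node star: hub aggregates the mean of the leaves
  star <- matrix(0, 4, 4); star[1, 2:4] <- 1; star <- star + t(star)
  h <- matrix(rnorm(8), 4, 2)
  p <- sage_params(2L, 3L)
  expect_lt(rel_err(sageLayerForward(star, h, p),
                    oracle_sage(star, h, p$W, p$b)), 1e-10)
  # every output row has unit norm (identity activation avoids the
  # all-negative rows that the rectifier legitimately zeroes out)
  p_id <- p; p_id$activation <- "identity"
  out <- sageLayerForward(star, h, p_id)
  expect_equal(unname(sqrt(rowSums(out^2))), rep(1, 4), tolerance = 1e-6)
  # with relu, rows are unit-norm or exactly zero
  nrm <- sqrt(rowSums(sageLayerForward(star, h, p)^2))
  expect_true(all(abs(nrm) < 1e-6 | abs(nrm - 1) < 1e-6))
  # isolated node: zero neighbor block, still unit norm
  iso <- matrix(0, 3, 3); iso[1, 2] <- iso[2, 1] <- 1
  out_iso <- sageLayerForward(iso, matrix(rnorm(6), 3, 2), p_id)
  expect_equal(sqrt(sum(out_iso[3, ]^2)), 1, tolerance = 1e-6)
  # random graphs vs oracle
  for (i in 1:20) {
    n <- sample(2:8, 1)
    a <- rand_adj(n)
    h <- matrix(rnorm(n * 2), n, 2)
    p <- sage_params(2L, 3L)
    expect_lt(rel_err(sageLayerForward(a, h, p),
                      oracle_sage(a, h, p$W, p$b)), 1e-10)
  }
})

test_that("assignment matrices are row-stochastic", {
  set.seed(32)
  for (i in 1:10) {
    n <- sample(3:9, 1)
    a <- rand_adj(n)
    x <- matrix(rnorm(n * 3), n, 3)
    p <- sage_params(3L, 4L)
    s <- diffpoolAssign(a, x, p)
    expect_true(all(s >= 0))
    expect_equal(unname(rowSums(s)), rep(1, n), tolerance = 1e-6)
  }
  # single cluster: the all-ones column
  a <- rand_adj(4)
  s1 <- diffpoolAssign(a, matrix(rnorm(8), 4, 2), sage_params(2L, 3L),
                       numClusters = 1L)
  expect_equal(unname(s1), matrix(1, 4, 1))
  # zero pooling-GNN output: uniform rows
  p0 <- list(W = matrix(0, 4, 3), b = matrix(0, 1, 3))
  s0 <- diffpoolAssign(a, matrix(rnorm(8), 4, 2), p0)
  expect_equal(unname(s0), matrix(1 / 3, 4, 3))
})

test_that("coarsening computes S^T Z and S^T A S", {
  # identity assignment leaves the graph unchanged
  z <- matrix(rnorm(9), 3, 3)
  cz <- diffpoolCoarsen(triangle_adj, z, diag(3))
  expect_equal(cz$features, z)
  expect_equal(cz$adjacency, triangle_adj)
  # hand example: 3 nodes to 2 clusters on a triangle
  s <- rbind(c(1, 0), c(1, 0), c(0, 1))
  cz2 <- diffpoolCoarsen(triangle_adj, z, s)
  expect_equal(cz2$adjacency, rbind(c(2, 2), c(2, 0)))
  # random instances vs a dense triple-product oracle; symmetry preserved
  set.seed(33)
  for (i in 1:20) {
    n <- sample(3:9, 1); k <- sample(1:3, 1)
    a <- rand_adj(n)
    s <- oracle_row_softmax(matrix(rnorm(n * k), n, k))
    z <- matrix(rnorm(n * 2), n, 2)
    cz <- diffpoolCoarsen(a, z, s)
    expect_lt(rel_err(cz$features, t(s) %*% z), 1e-12)
    expect_lt(rel_err(cz$adjacency, t(s) %*% a %*% s), 1e-12)
    expect_equal(cz$adjacency, t(cz$adjacency), tolerance = 1e-12)
    expect_true(all(cz$adjacency >= -1e-12))
    # mass identity: 1' S' A S 1 equals the S1-weighted quadratic form,
    # which for row-stochastic S is the total edge weight of A
    q <- as.numeric(t(rowSums(s)) %*% a %*% rowSums(s))
    expect_equal(sum(cz$adjacency), q, tolerance = 1e-9)
    expect_equal(q, sum(a), tolerance = 1e-9)
  }
})

test_that("forward pass shapes, invariance, and degenerate pooling ratios", {
  set.seed(34)
  gs <- lapply(1:3, function(k) rand_graph(sample(5:9, 1), id = paste0("g", k)))
  b <- batchGraphs(gs)
  m <- diffpoolModel(3L, 2L, 3L, hidden = 8L, maxNodes = 9L, seed = 11L)
  out <- diffpoolForward(b, m)
  expect_equal(nrow(nodeScores(out)), nrow(b@features))  # node rows survive pooling
  expect_equal(nrow(graphScores(out)), 3L)
  expect_equal(ncol(nodeEmbedding(out)), 8L)

  # permutation invariance of graph scores
  g <- gs[[1]]
  perm <- sample(numNodes(g))
  gp <- LabeledGraph(adjacency(g)[perm, perm],
                     nodeFeatures = nodeFeatures(g)[perm, , drop = FALSE],
                     nodeLabels = nodeLabels(g)[perm], graphLabel = graphLabel(g))
  o1 <- diffpoolForward(batchGraphs(list(g)), m)
  o2 <- diffpoolForward(batchGraphs(list(gp)), m)
  expect_lt(max(abs(graphScores(o1) - graphScores(o2))), 1e-5)

  # cluster_ratio = 1 keeps every node as its own cluster slot
  m1 <- diffpoolModel(3L, 2L, 3L, hidden = 8L, clusterRatio = 1, maxNodes = 9L,
                      seed = 12L)
  expect_equal(m1$maxClusters, 9L)
  out1 <- diffpoolForward(b, m1)
  expect_equal(nrow(graphScores(out1)), 3L)

  # evaluation-mode batch independence
  alone <- diffpoolForward(batchGraphs(list(g)), m)
  expect_equal(graphScores(alone)[1, ], graphScores(out)[1, ], tolerance = 1e-10)
})

test_that("node task gradients do not reach post-pool parameters", {
  set.seed(35)
  b <- rand_batch(3L, nmax = 8L)
  m <- diffpoolModel(3L, 2L, 3L, hidden = 6L, maxNodes = 8L, seed = 13L)
  # node-only objective: subtract the pure graph loss gradients
  snap <- bn_snapshot(m)
  both <- lossAndGradients(b, m, alpha = 1)
  bn_restore(m, snap)
  graph_only <- lossAndGradients(b, m, alpha = 0)
  bn_restore(m, snap)
  for (nm in grep("^(post|pool|embed|graph_head)", names(m$par), value = TRUE)) {
    expect_equal(both$grads[[nm]], graph_only$grads[[nm]], tolerance = 1e-12)
  }
  # while shared pre-pool layers DO receive node-task gradient
  expect_gt(max(abs(both$grads[["pre1.W"]] - graph_only$grads[["pre1.W"]])), 1e-8)
  # and the node head receives gradient only from the node task
  expect_true(all(graph_only$grads[["node_head.W"]] == 0))
})

test_that("diffpool autodiff forward agrees with the plain forward pass", {
  set.seed(36)
  b <- rand_batch(3L, nmax = 7L)
  m <- diffpoolModel(3L, 2L, 3L, hidden = 6L, maxNodes = 7L, seed = 14L)
  for (training in c(TRUE, FALSE)) {
    snap <- bn_snapshot(m)
    tape <- mtgraph:::ad_tape()
    ctx <- mtgraph:::ad_param_ctx(tape)
    ad_out <- mtgraph:::diffpool_forward_ad(b, m, tape, ctx, training)
    bn_restore(m, snap)
    plain <- diffpoolForward(b, m, training)
    bn_restore(m, snap)
    expect_equal(mtgraph:::ad_value(ad_out$graphScores), graphScores(plain),
                 tolerance = 1e-10)
    expect_equal(mtgraph:::ad_value(ad_out$nodeScores), nodeScores(plain),
                 tolerance = 1e-10)
  }
})
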