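test_that("cross-entropy losses match the direct softmax-log oracle", {
  set.seed(41)
  # perfect prediction: loss 0
  sure <- matrix(c(100, 0, 0, 100), 2, byrow = TRUE)
  expect_equal(graphCrossEntropy(sure, c(0L, 1L)), 0, tolerance = 1e-10)
  # uniform scores: sum variant gives N log C, mean variant log C
  u <- matrix(0, 5, 3)
  expect_equal(nodeCrossEntropy(u, rep(0L, 5), reduction = "sum"), 5 * log(3))
  expect_equal(nodeCrossEntropy(u, rep(0L, 5)), log(3))
  # random cases vs oracle, with and without mask
  for (i in 1:20) {
    n <- sample(2:7, 1); c_ <- sample(2:4, 1)
    sc <- matrix(rnorm(n * c_, sd = 2), n, c_)
    lab <- sample.int(c_, n, replace = TRUE) - 1L
    mask <- runif(n) < 0.7
    if (!any(mask)) mask[1] <- TRUE
    for (red in c("mean", "sum")) {
      expect_equal(nodeCrossEntropy(sc, lab, mask, red),
                   oracle_xent(sc, lab, mask, red), tolerance = 1e-8)
    }
    expect_equal(graphCrossEntropy(sc, lab, "mean"),
                 oracle_xent(sc, lab, NULL, "mean"), tolerance = 1e-8)
  }
  # all-masked: defined as zero with a warning
  expect_warning(z <- nodeCrossEntropy(u, rep(0L, 5), rep(FALSE, 5)), "unmasked")
  expect_equal(z, 0)
})

test_that("joint loss is linear in the node loss with weight alpha", {
  expect_equal(jointLoss(0.5, 0.25, 1), 0.75)
  expect_equal(jointLoss(0.5, 0.25, 0), 0.5)   # alpha = 0: single-task
  expect_equal(jointLoss(0.7, 0, 2), 0.7)
  expect_error(jointLoss(1, 1, -0.1), "alpha")
  # monotone non-decreasing in alpha for positive node loss
  ls <- vapply(c(0, 0.5, 0.75, 1.25, 1.5, 2), function(a) jointLoss(1, 0.3, a),
               numeric(1))
  expect_true(all(diff(ls) >= 0))
})

test_that("learning-rate schedule halves every 50 epochs from 0.01", {
  cfg <- trainConfig()
  expect_equal(lrAtEpoch(cfg, 0L), 0.01)
  expect_equal(lrAtEpoch(cfg, 49L), 0.01)
  expect_equal(lrAtEpoch(cfg, 50L), 0.005)
  expect_equal(lrAtEpoch(cfg, 100L), 0.0025)
  expect_equal(lrAtEpoch(cfg, 349L), 0.01 * 0.5^6)
  expect_error(lrAtEpoch(cfg, 350L), "epoch")
  expect_error(lrAtEpoch(cfg, -1L), "epoch")
})

test_that("joint-loss gradients pass a finite-difference check", {
  set.seed(42)
  # 6-node fixture: three 2-node graphs, so every batch-normalized layer
  # (including the pooled clusters) sees several rows and the loss is
  # smooth at the test point -- a requirement for finite differences
  g6 <- lapply(1:3, function(k) rand_graph(2L, d = 2L, p = 1, id = paste0("g", k)))
  b <- batchGraphs(g6)
  for (kind in c("gin", "diffpool")) {
    m <- if (kind == "gin") {
      ginModel(2L, 2L, 3L, numLayers = 2L, hidden = 4L, seed = 15L)
    } else {
      diffpoolModel(2L, 2L, 3L, hidden = 4L, maxNodes = 2L, seed = 16L)
    }
    snap <- bn_snapshot(m)
    lg <- lossAndGradients(b, m, alpha = 1)
    bn_restore(m, snap)
    for (nm in names(m$par)) {
      idx <- sample(length(m$par[[nm]]), min(2L, length(m$par[[nm]])))
      for (i in idx) {
        num <- fd_gradient(b, m, nm, i, alpha = 1)
        an <- lg$grads[[nm]][i]
        denom <- max(abs(num), abs(an))
        if (denom > 1e-6) {
          expect_lt(abs(num - an) / denom, 1e-4)
        } else {
          expect_lt(abs(num - an), 1e-6)
        }
      }
    }
  }
})

test_that("training is reproducible and alpha = 0 freezes the node head", {
  d <- generateDataset(synthConfig(numGraphs = 24L, nodesMin = 5L,
                                   nodesMax = 8L, seed = 17L))
  tr <- methods::initialize(d, graphs = graphs(d)[1:18])
  va <- methods::initialize(d, graphs = graphs(d)[19:24])
  cfg <- trainConfig(alpha = 1, epochs = 3L, hidden = 6L, numLayers = 2L,
                     seed = 100L)
  r1 <- trainFold(tr, va, cfg)
  r2 <- trainFold(tr, va, cfg)
  expect_identical(r1$trace$trainLoss, r2$trace$trainLoss)  # determinism
  expect_identical(r1$model$par, r2$model$par)

  cfg0 <- cfg; cfg0$alpha <- 0
  r0 <- trainFold(tr, va, cfg0)
  m_init <- mtgraph:::new_model_for(
    cfg0, featureDim(d), numGraphClasses(d), numNodeClasses(d), 8L,
    seed = withr::with_seed(cfg0$seed, sample.int(.Machine$integer.max, 1L)))
  # node head receives no gradient at alpha = 0: unchanged from init
  expect_identical(r0$model$par[["node_head.W"]], m_init$par[["node_head.W"]])
  # but the shared trunk trains
  expect_gt(max(abs(r0$model$par[["gin1.W1"]] - m_init$par[["gin1.W1"]])), 1e-6)
})

test_that("alpha = 0 trajectory equals single-task training with masked nodes", {
  # the same dataset with all node labels hidden: node loss identically
  # masked out, so the L_G trace must coincide with the alpha = 0 run
  d <- generateDataset(synthConfig(numGraphs = 20L, nodesMin = 5L,
                                   nodesMax = 8L, seed = 18L))
  d_masked <- d
  d_masked@graphs <- lapply(graphs(d), function(g) {
    g@nodeLabelMask <- rep(FALSE, numNodes(g))
    g
  })
  tr <- function(ds, alpha) {
    cfg <- trainConfig(alpha = alpha, epochs = 3L, hidden = 6L,
                       numLayers = 2L, seed = 200L)
    trainFold(methods::initialize(ds, graphs = graphs(ds)[1:16]),
              methods::initialize(ds, graphs = graphs(ds)[17:20]), cfg)
  }
  r_zero <- tr(d, 0)
  r_masked <- tr(d_masked, 1.5)
  expect_equal(r_zero$trace$trainLossGraph, r_masked$trace$trainLossGraph,
               tolerance = 1e-6)
  shared <- setdiff(names(r_zero$model$par), c("node_head.W", "node_head.b"))
  for (nm in shared) {
    expect_equal(r_zero$model$par[[nm]], r_masked$model$par[[nm]],
                 tolerance = 1e-10)
  }
})

test_that("stratified cross-validation splits evenly and deterministically", {
  d <- generateDataset(synthConfig(numGraphs = 100L, nodesMin = 4L,
                                   nodesMax = 6L, seed = 19L))
  assign1 <- mtgraph:::stratified_folds(d, 10L, seed = 7L)
  expect_equal(unname(table(assign1)), rep(10L, 10L), ignore_attr = TRUE)
  # class balance: each fold's class-1 share within 2 of the global share
  labels <- vapply(graphs(d), graphLabel, integer(1))
  per_fold <- tapply(labels, assign1, sum)
  expect_lte(diff(range(per_fold)), 2L)
  # fold membership keyed by graph id: invariant to dataset order
  perm <- sample(100L)
  d_shuf <- methods::initialize(d, graphs = graphs(d)[perm])
  assign2 <- mtgraph:::stratified_folds(d_shuf, 10L, seed = 7L)
  expect_identical(assign1[perm], assign2)
})

test_that("cross-validation aggregates per-fold accuracies", {
  d <- generateDataset(synthConfig(numGraphs = 30L, nodesMin = 4L,
                                   nodesMax = 6L, seed = 20L))
  cfg <- trainConfig(alpha = 1, epochs = 2L, folds = 3L, hidden = 6L,
                     numLayers = 2L, seed = 5L)
  logdir <- withr::local_tempdir()
  rep_ <- crossValidate(d, cfg, logDir = logdir)
  expect_equal(nrow(rep_$folds), 3L)
  expect_equal(rep_$folds$valSize, rep(10L, 3L))
  expect_equal(rep_$meanGraphAcc, mean(rep_$folds$bestGraphAcc))
  expect_true(all(rep_$folds$bestGraphAcc >= 0 & rep_$folds$bestGraphAcc <= 1))
  expect_true(file.exists(file.path(logdir, "cv_summary.tsv")))
  expect_true(file.exists(file.path(logdir, "fold01_trace.tsv")))
  expect_error(crossValidate(d, trainConfig(folds = 40L)), "smaller")
})
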