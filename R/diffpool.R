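# Multi-task differentiable-pooling model (MT-DIFFPOOL).
#
# Two GraphSAGE layers (mean aggregation, batchnorm, ReLU, row-wise l2
# normalization) are shared between the tasks. The node head taps the
# pre-pool SAGE output, so node classification depends only on the shared
# layers. The graph branch continues with one differentiable pooling step --
# a row-stochastic soft assignment S from a pooling GNN, coarsening
# X' = S^T Z and A' = S^T A S computed per graph so clusters never span
# graphs -- followed by three SAGE-style convolutions on the weighted
# coarsened adjacency, a sum readout over clusters, and the graph head.
# The number of clusters per graph is ceil(clusterRatio * n) with a floor of
# one; the default ratio 0.1 removes 90% of the nodes.

row_l2_normalize <- function(x, eps = 1e-12) {
  x / pmax(sqrt(rowSums(x^2)), eps)
}

# mean over neighbors; zero rows for isolated nodes (weighted A supported)
neighbor_mean <- function(adjacency, h) {
  s <- as.matrix(adjacency %*% h)
  deg <- as.vector(adjacency %*% matrix(1, nrow(h), 1))
  s / pmax(deg, 1e-12)
}

#' One GraphSAGE layer forward pass (mean aggregator)
#'
#' Each node's representation is concatenated with the mean of its neighbor
#' rows (zero vector for isolated nodes), passed through an affine map,
#' optional batch normalization, the activation, and optional row-wise l2
#' normalization. Weighted adjacencies (as produced by pooling) are
#' supported: the "mean" is then the degree-weighted average.
#'
#' @param adjacency N x N (sparse or dense, possibly weighted) adjacency.
#' @param hPrev N x w matrix.
#' @param params list with `W` (2w x w'), `b`, optional batchnorm `g`/`be`
#'   (+ stored `bn` statistics), `activation` ("relu" or "identity",
#'   default "relu"), `normalize` (default TRUE).
#' @param training batch-statistics mode for batch normalization.
#' @return N x w' matrix; rows have unit norm when `normalize` is on.
#' @export
sageLayerForward <- function(adjacency, hPrev, params, training = FALSE) {
  hPrev <- as.matrix(hPrev)
  if (nrow(adjacency) != nrow(hPrev)) {
    stop("dimension error: adjacency and hPrev row counts differ")
  }
  m <- neighbor_mean(adjacency, hPrev)
  z <- cbind(hPrev, m)
  if (ncol(z) != nrow(params$W)) {
    stop("dimension error: concatenated width ", ncol(z),
         " does not match W rows ", nrow(params$W))
  }
  z <- col_plus(z %*% params$W, as.vector(params$b))
  if (!is.null(params$g)) {
    z <- bn_plain(z, params$g, params$be, params$bn, training)
  }
  if (is.null(params$activation) || params$activation == "relu") z <- pmax(z, 0)
  if (is.null(params$normalize) || isTRUE(params$normalize)) {
    z <- row_l2_normalize(z)
  }
  z
}

#' Soft cluster assignment for differentiable pooling
#'
#' Runs the pooling GNN (a SAGE-style layer with identity activation and no
#' normalization) on `(A, X)` and applies a row-wise softmax, yielding the
#' row-stochastic assignment matrix S whose column count is the target
#' cluster count.
#'
#' @param adjacency n x n adjacency at the current level.
#' @param x n x w feature/embedding matrix.
#' @param params pooling-GNN parameters as for [sageLayerForward()]; the
#'   output width of `W` is the number of clusters.
#' @param numClusters optionally keep only the first `numClusters` logit
#'   columns before the softmax (per-graph cluster budgets).
#' @return n x numClusters matrix with nonnegative rows summing to 1.
#' @export
diffpoolAssign <- function(adjacency, x, params, numClusters = NULL) {
  p <- params
  p$activation <- "identity"
  p$normalize <- FALSE
  logits <- sageLayerForward(adjacency, x, p)
  if (!is.null(numClusters)) {
    logits <- logits[, seq_len(numClusters), drop = FALSE]
  }
  row_softmax(logits)
}

#' Differentiable-pooling coarsening step
#'
#' Given the node embeddings Z and the row-stochastic assignment S, forms the
#' cluster features `X' = S^T Z` and the coarsened adjacency `A' = S^T A S`.
#' A' is symmetric whenever A is.
#'
#' @param adjacency n x n adjacency.
#' @param z n x w embedding matrix.
#' @param s n x k row-stochastic assignment.
#' @return list with elements `features` (k x w) and `adjacency` (k x k).
#' @export
diffpoolCoarsen <- function(adjacency, z, s) {
  z <- as.matrix(z); s <- as.matrix(s)
  if (nrow(z) != nrow(s) || nrow(adjacency) != nrow(s)) {
    stop("dimension error: adjacency, z and s must agree on the node count")
  }
  list(features = crossprod(s, z),
       adjacency = crossprod(s, as.matrix(adjacency %*% s)))
}

#' Initialize an MT-DIFFPOOL model
#'
#' @param featureDim input feature width d.
#' @param numGraphClasses,numNodeClasses output class counts.
#' @param hidden hidden width of every SAGE layer (default 64).
#' @param clusterRatio fraction of nodes kept by pooling (default 0.1,
#'   i.e. a 90 percent reduction); per graph the cluster count is
#'   `max(1, ceiling(clusterRatio * n))`.
#' @param maxNodes largest node count the model will see; sizes the pooling
#'   GNN output (the cluster-count ceiling).
#' @param nodeTap which pre-pool SAGE layer feeds the node head (1 or 2;
#'   default 2, the layer immediately before pooling).
#' @param seed seed for weight initialization.
#' @return A list of class `"mtgraphModel"`.
#' @export
diffpoolModel <- function(featureDim, numGraphClasses, numNodeClasses,
                          hidden = 64L, clusterRatio = 0.1, maxNodes,
                          nodeTap = 2L, seed = 1L) {
  stopifnot(featureDim >= 1L, numGraphClasses >= 2L,
            clusterRatio > 0, clusterRatio <= 1, maxNodes >= 1L,
            nodeTap %in% c(1L, 2L))
  withr::local_seed(seed)
  kmax <- max(1L, as.integer(ceiling(clusterRatio * maxNodes)))
  par <- list()
  sage_par <- function(prefix, w_in, w_out, bn = TRUE) {
    par[[paste0(prefix, ".W")]] <<- glorot(2L * w_in, w_out)
    par[[paste0(prefix, ".b")]] <<- matrix(0, 1, w_out)
    if (bn) {
      par[[paste0(prefix, ".g")]] <<- matrix(1, 1, w_out)
      par[[paste0(prefix, ".be")]] <<- matrix(0, 1, w_out)
    }
  }
  sage_par("pre1", featureDim, hidden)
  sage_par("pre2", hidden, hidden)
  sage_par("pool", hidden, kmax, bn = FALSE)
  sage_par("embed", hidden, hidden)
  for (l in 1:3) sage_par(sprintf("post%d", l), hidden, hidden)
  par[["graph_head.W"]] <- glorot(hidden, numGraphClasses)
  par[["graph_head.b"]] <- matrix(0, 1, numGraphClasses)
  if (numNodeClasses >= 2L) {
    par[["node_head.W"]] <- glorot(hidden, numNodeClasses)
    par[["node_head.b"]] <- matrix(0, 1, numNodeClasses)
  }
  bn <- new_bn_state()
  for (prefix in c("pre1", "pre2", "embed", "post1", "post2", "post3")) {
    bn$stats[[paste0(prefix, ".bn")]] <-
      list(mean = numeric(hidden), var = rep(1, hidden))
  }
  structure(list(kind = "diffpool", par = par, bn = bn,
                 featureDim = as.integer(featureDim),
                 numGraphClasses = as.integer(numGraphClasses),
                 numNodeClasses = as.integer(numNodeClasses),
                 hidden = as.integer(hidden), clusterRatio = clusterRatio,
                 maxClusters = kmax, nodeTap = as.integer(nodeTap)),
            class = "mtgraphModel")
}

diffpool_sage_params <- function(model, prefix) {
  list(W = model$par[[paste0(prefix, ".W")]],
       b = model$par[[paste0(prefix, ".b")]],
       g = model$par[[paste0(prefix, ".g")]],
       be = model$par[[paste0(prefix, ".be")]],
       bn = model$bn$stats[[paste0(prefix, ".bn")]])
}

clusters_for <- function(ratio, n) max(1L, as.integer(ceiling(ratio * n)))

#' MT-DIFFPOOL forward pass
#'
#' Node scores are computed from the pre-pool SAGE tap; the graph branch
#' pools each graph to `ceil(clusterRatio * n)` clusters (assignments are
#' computed within graph boundaries), runs three post-pool SAGE-style
#' convolutions on the weighted coarsened adjacency, sums over clusters per
#' graph, and applies the graph head. Scores are raw (pre-softmax).
#'
#' @param batch a [GraphBatch-class].
#' @param model a [diffpoolModel()] object.
#' @param training batch-statistics mode for batch normalization.
#' @return A [ModelOutput-class]; `perLayerNodeReps` holds the raw features
#'   and the two pre-pool SAGE outputs.
#' @export
diffpoolForward <- function(batch, model, training = FALSE) {
  stopifnot(model$kind == "diffpool")
  if (ncol(batch@features) != model$featureDim) {
    stop("dimension error: batch feature width ", ncol(batch@features),
         " != model featureDim ", model$featureDim)
  }
  A <- batch@blockAdjacency
  B <- length(batch@graphLabels)
  h1 <- sageLayerForward(A, batch@features, diffpool_sage_params(model, "pre1"), training)
  h2 <- sageLayerForward(A, h1, diffpool_sage_params(model, "pre2"), training)
  tap <- if (model$nodeTap == 1L) h1 else h2
  ns <- if (!is.null(model$par[["node_head.W"]])) {
    sweep(tap %*% model$par[["node_head.W"]], 2L,
          as.vector(model$par[["node_head.b"]]), "+")
  } else matrix(0, nrow(tap), 0L)

  pool_logits <- {
    p <- diffpool_sage_params(model, "pool")
    p$activation <- "identity"; p$normalize <- FALSE
    sageLayerForward(A, h2, p)
  }
  z <- sageLayerForward(A, h2, diffpool_sage_params(model, "embed"), training)

  xs <- list(); as_ <- list(); memb <- integer()
  a_dense <- as.matrix(A)
  for (k in seq_len(B)) {
    idx <- which(batch@graphMembership == k)
    kg <- clusters_for(model$clusterRatio, length(idx))
    s <- row_softmax(pool_logits[idx, seq_len(kg), drop = FALSE])
    cz <- diffpoolCoarsen(a_dense[idx, idx, drop = FALSE],
                          z[idx, , drop = FALSE], s)
    xs[[k]] <- cz$features
    as_[[k]] <- cz$adjacency
    memb <- c(memb, rep(k, kg))
  }
  xc <- do.call(rbind, xs)
  ac <- as.matrix(Matrix::bdiag(lapply(as_, function(m) Matrix::Matrix(m))))
  hc <- xc
  for (l in 1:3) {
    hc <- sageLayerForward(ac, hc, diffpool_sage_params(model, sprintf("post%d", l)),
                           training)
  }
  rG <- group_rowsum(hc, memb, B)
  gs <- sweep(rG %*% model$par[["graph_head.W"]], 2L,
              as.vector(model$par[["graph_head.b"]]), "+")
  new("ModelOutput", nodeScores = ns, graphScores = gs,
      perLayerNodeReps = list(batch@features, h1, h2),
      graphEmbedding = rG, nodeEmbedding = tap)
}

# ---- autodiff path (training) ----------------------------------------------

# One SAGE layer on an ad graph; adjacency may be a fixed matrix (constant)
# or an ad node (post-pool, gradients flow through it).
sage_ad <- function(tape, ctx, model, prefix, adjacency, h, training,
                    activation = "relu", normalize = TRUE, bn = TRUE) {
  if (inherits(adjacency, "ad")) {
    ones <- ad_leaf(tape, matrix(1, nrow(ad_value(h)), 1))
    m <- ad_coldiv(ad_matmul(adjacency, h), ad_matmul(adjacency, ones))
  } else {
    s <- ad_lmul_const(adjacency, h)
    deg <- matrix(pmax(as.vector(adjacency %*% matrix(1, nrow(ad_value(h)), 1)),
                       1e-12), ncol = 1)
    m <- ad_coldiv(s, ad_leaf(tape, deg))
  }
  W <- ad_param(ctx, paste0(prefix, ".W"), model$par[[paste0(prefix, ".W")]])
  b <- ad_param(ctx, paste0(prefix, ".b"), model$par[[paste0(prefix, ".b")]])
  zc <- ad_addbias(ad_matmul(ad_cbind(list(h, m)), W), b)
  if (bn && !is.null(model$par[[paste0(prefix, ".g")]])) {
    g <- ad_param(ctx, paste0(prefix, ".g"), model$par[[paste0(prefix, ".g")]])
    be <- ad_param(ctx, paste0(prefix, ".be"), model$par[[paste0(prefix, ".be")]])
    zc <- ad_batchnorm(zc, g, be, model$bn, paste0(prefix, ".bn"), training)
  }
  if (activation == "relu") zc <- ad_relu(zc)
  if (normalize) zc <- ad_l2norm_rows(zc)
  zc
}

diffpool_forward_ad <- function(batch, model, tape, ctx, training) {
  A <- batch@blockAdjacency
  B <- length(batch@graphLabels)
  x <- ad_leaf(tape, batch@features)
  h1 <- sage_ad(tape, ctx, model, "pre1", A, x, training)
  h2 <- sage_ad(tape, ctx, model, "pre2", A, h1, training)
  tap <- if (model$nodeTap == 1L) h1 else h2
  ns <- NULL
  if (!is.null(model$par[["node_head.W"]])) {
    nW <- ad_param(ctx, "node_head.W", model$par[["node_head.W"]])
    nb <- ad_param(ctx, "node_head.b", model$par[["node_head.b"]])
    ns <- ad_addbias(ad_matmul(tap, nW), nb)
  }
  pool_logits <- sage_ad(tape, ctx, model, "pool", A, h2, training,
                         activation = "identity", normalize = FALSE, bn = FALSE)
  z <- sage_ad(tape, ctx, model, "embed", A, h2, training)

  a_dense <- as.matrix(A)
  xs <- list(); as_ <- list(); memb <- integer()
  for (k in seq_len(B)) {
    idx <- which(batch@graphMembership == k)
    kg <- clusters_for(model$clusterRatio, length(idx))
    lg <- ad_rowslice(pool_logits, idx)
    if (kg < ncol(ad_value(pool_logits))) lg <- ad_colslice(lg, seq_len(kg))
    s <- ad_rowsoftmax(lg)
    st <- ad_t(s)
    zg <- ad_rowslice(z, idx)
    ag <- ad_leaf(tape, a_dense[idx, idx, drop = FALSE])
    xs[[k]] <- ad_matmul(st, zg)
    as_[[k]] <- ad_matmul(st, ad_matmul(ag, s))
    memb <- c(memb, rep(k, kg))
  }
  xc <- ad_rbind(xs)
  ac <- ad_blockdiag(as_)
  hc <- xc
  for (l in 1:3) {
    hc <- sage_ad(tape, ctx, model, sprintf("post%d", l), ac, hc, training)
  }
  rG <- ad_groupsum(hc, memb, B)
  gW <- ad_param(ctx, "graph_head.W", model$par[["graph_head.W"]])
  gb <- ad_param(ctx, "graph_head.b", model$par[["graph_head.b"]])
  gs <- ad_addbias(ad_matmul(rG, gW), gb)
  list(graphScores = gs, nodeScores = ns, rG = rG, rv = tap)
}
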