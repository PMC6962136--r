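# Multi-task Graph Isomorphism Network (MT-GIN).
#
# Layer update: h_v <- MLP((1 + eps) * h_v + sum_{u in N(v)} h_u), with a
# two-layer MLP (affine -> batchnorm -> ReLU -> affine -> batchnorm -> ReLU).
# The graph representation r_G concatenates, over layers 0..L (layer 0 = raw
# features), the per-graph sum of node rows; the node representation r_v
# concatenates the per-layer node rows. Each representation feeds one affine
# classification head; every other parameter is shared between the tasks.

glorot <- function(fan_in, fan_out) {
  a <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(fan_in * fan_out, -a, a), fan_in, fan_out)
}

new_bn_state <- function() {
  e <- new.env(parent = emptyenv())
  e$stats <- list()
  e
}

#' Initialize an MT-GIN model
#'
#' @param featureDim input feature width d.
#' @param numGraphClasses,numNodeClasses output class counts.
#' @param numLayers number of message-passing layers (default 5).
#' @param hidden hidden width of every MLP layer (default 64).
#' @param epsilon the self-weight offset; fixed, default 0.
#' @param trainableEpsilon learn epsilon per layer instead of fixing it.
#' @param seed seed for weight initialization (Glorot uniform).
#' @return A list of class `"mtgraphModel"` with the flat named parameter
#'   list in `$par` and batch-normalization running statistics in `$bn`.
#' @export
ginModel <- function(featureDim, numGraphClasses, numNodeClasses,
                     numLayers = 5L, hidden = 64L, epsilon = 0,
                     trainableEpsilon = FALSE, seed = 1L) {
  stopifnot(featureDim >= 1L, numGraphClasses >= 2L, numLayers >= 1L)
  withr::local_seed(seed)
  par <- list()
  w_in <- featureDim
  for (l in seq_len(numLayers)) {
    p <- sprintf("gin%d.", l)
    par[[paste0(p, "W1")]] <- glorot(w_in, hidden)
    par[[paste0(p, "b1")]] <- matrix(0, 1, hidden)
    par[[paste0(p, "g1")]] <- matrix(1, 1, hidden)
    par[[paste0(p, "be1")]] <- matrix(0, 1, hidden)
    par[[paste0(p, "W2")]] <- glorot(hidden, hidden)
    par[[paste0(p, "b2")]] <- matrix(0, 1, hidden)
    par[[paste0(p, "g2")]] <- matrix(1, 1, hidden)
    par[[paste0(p, "be2")]] <- matrix(0, 1, hidden)
    if (trainableEpsilon) par[[paste0(p, "eps")]] <- matrix(epsilon, 1, 1)
    w_in <- hidden
  }
  cat_width <- featureDim + numLayers * hidden
  par[["graph_head.W"]] <- glorot(cat_width, numGraphClasses)
  par[["graph_head.b"]] <- matrix(0, 1, numGraphClasses)
  if (numNodeClasses >= 2L) {
    par[["node_head.W"]] <- glorot(cat_width, numNodeClasses)
    par[["node_head.b"]] <- matrix(0, 1, numNodeClasses)
  }
  bn <- new_bn_state()
  for (l in seq_len(numLayers)) {
    for (s in c("bn1", "bn2")) {
      bn$stats[[sprintf("gin%d.%s", l, s)]] <-
        list(mean = numeric(hidden), var = rep(1, hidden))
    }
  }
  structure(list(kind = "gin", par = par, bn = bn,
                 featureDim = as.integer(featureDim),
                 numGraphClasses = as.integer(numGraphClasses),
                 numNodeClasses = as.integer(numNodeClasses),
                 numLayers = as.integer(numLayers), hidden = as.integer(hidden),
                 epsilon = epsilon, trainableEpsilon = trainableEpsilon),
            class = "mtgraphModel")
}

#' @export
print.mtgraphModel <- function(x, ...) {
  np <- sum(vapply(x$par, length, integer(1)))
  cat(sprintf("mtgraphModel (%s): d=%d, hidden=%d, C_G=%d, C_v=%d, %d parameters\n",
              x$kind, x$featureDim, x$hidden, x$numGraphClasses,
              x$numNodeClasses, np))
  invisible(x)
}

# plain (non-autodiff) batchnorm; `stats` is list(mean=, var=) or NULL.
bn_plain <- function(x, gamma, beta, stats, training, eps = 1e-5) {
  if (training || is.null(stats)) {
    mu <- colMeans(x)
    va <- colMeans(col_plus(x, -mu)^2)
  } else {
    mu <- stats$mean
    va <- stats$var
  }
  xhat <- col_times(col_plus(x, -mu), 1 / sqrt(va + eps))
  col_affine(xhat, as.vector(gamma), as.vector(beta))
}

#' One GIN layer forward pass
#'
#' Aggregates `(1 + eps) * h_v + sum of neighbor rows` along the batch's
#' block adjacency and applies the layer's two-layer MLP. When the parameter
#' list carries no weights (`W1` absent) the MLP is the identity, which
#' exposes the bare aggregation.
#'
#' @param batch a [GraphBatch-class].
#' @param hPrev N x w matrix of node representations.
#' @param params layer parameter list: optional `W1`, `b1`, `g1`, `be1`,
#'   `W2`, `b2`, `g2`, `be2` (batchnorm scale/shift; omit `g1`/`g2` to skip
#'   batch normalization), `eps` (default 0), and optional `bn1`/`bn2`
#'   running statistics used when `training = FALSE`.
#' @param training use batch statistics in batch normalization.
#' @return N x w' matrix.
#' @examples
#' b <- batchGraphs(list(LabeledGraph(matrix(c(0,1,0, 1,0,1, 0,1,0), 3),
#'                                    nodeFeatures = matrix(1, 3, 1))))
#' ginLayerForward(b, matrix(1, 3, 1), list(eps = 0))  # path: 2, 3, 2
#' @export
ginLayerForward <- function(batch, hPrev, params, training = FALSE) {
  stopifnot(is(batch, "GraphBatch"))
  hPrev <- as.matrix(hPrev)
  if (nrow(hPrev) != nrow(batch@features)) {
    stop("dimension error: hPrev must have one row per batch node")
  }
  eps <- if (is.null(params$eps)) 0 else as.numeric(params$eps)
  h <- (1 + eps) * hPrev + as.matrix(batch@blockAdjacency %*% hPrev)
  if (is.null(params$W1)) return(h)
  if (ncol(h) != nrow(params$W1)) {
    stop("dimension error: width ", ncol(h), " does not match W1 rows ",
         nrow(params$W1))
  }
  z <- col_plus(h %*% params$W1, as.vector(params$b1))
  if (!is.null(params$g1)) {
    z <- bn_plain(z, params$g1, params$be1, params$bn1, training)
  }
  z <- pmax(z, 0)
  z <- col_plus(z %*% params$W2, as.vector(params$b2))
  if (!is.null(params$g2)) {
    z <- bn_plain(z, params$g2, params$be2, params$bn2, training)
  }
  pmax(z, 0)
}

#' Concatenated sum readout over layers
#'
#' For each graph in the batch, sums the node rows of every per-layer
#' representation and concatenates the sums across layers, yielding the graph
#' representation r_G.
#'
#' @param batch a [GraphBatch-class].
#' @param perLayerReps list of N x w_l matrices (layers 0..L).
#' @return B x (sum of widths) matrix.
#' @export
graphReadout <- function(batch, perLayerReps) {
  stopifnot(is(batch, "GraphBatch"), length(perLayerReps) >= 1L)
  B <- length(batch@graphLabels)
  N <- nrow(batch@features)
  parts <- lapply(perLayerReps, function(h) {
    h <- as.matrix(h)
    if (nrow(h) != N) stop("dimension error: representation rows != batch nodes")
    group_rowsum(h, batch@graphMembership, B)
  })
  do.call(cbind, parts)
}

#' Concatenated per-node representation over layers
#'
#' Horizontal concatenation of the per-layer node matrices in layer order;
#' row v is the node representation r_v.
#'
#' @param perLayerReps list of N x w_l matrices.
#' @return N x (sum of widths) matrix.
#' @export
nodeConcat <- function(perLayerReps) {
  stopifnot(length(perLayerReps) >= 1L)
  n <- nrow(as.matrix(perLayerReps[[1]]))
  mats <- lapply(perLayerReps, function(h) {
    h <- as.matrix(h)
    if (nrow(h) != n) stop("dimension error: row-count mismatch across layers")
    h
  })
  do.call(cbind, mats)
}

# Extract the plain-layer parameter list for layer l of a gin model,
# including current running statistics.
gin_layer_params <- function(model, l) {
  p <- sprintf("gin%d.", l)
  eps <- if (model$trainableEpsilon) as.numeric(model$par[[paste0(p, "eps")]])
         else model$epsilon
  list(W1 = model$par[[paste0(p, "W1")]], b1 = model$par[[paste0(p, "b1")]],
       g1 = model$par[[paste0(p, "g1")]], be1 = model$par[[paste0(p, "be1")]],
       W2 = model$par[[paste0(p, "W2")]], b2 = model$par[[paste0(p, "b2")]],
       g2 = model$par[[paste0(p, "g2")]], be2 = model$par[[paste0(p, "be2")]],
       eps = eps,
       bn1 = model$bn$stats[[paste0(p, "bn1")]],
       bn2 = model$bn$stats[[paste0(p, "bn2")]])
}

#' MT-GIN forward pass
#'
#' Runs the full multi-task forward computation: stacked GIN layers, the
#' concatenated sum readout (graph task) and concatenated node
#' representation (node task), and both affine heads. Scores are raw
#' (pre-softmax); the losses own the softmax.
#'
#' @param batch a [GraphBatch-class].
#' @param model a [ginModel()] object.
#' @param training batch-statistics mode for batch normalization; with
#'   `training = FALSE` (default) stored running statistics are used.
#' @return A [ModelOutput-class].
#' @export
ginForward <- function(batch, model, training = FALSE) {
  stopifnot(model$kind == "gin")
  if (ncol(batch@features) != model$featureDim) {
    stop("dimension error: batch feature width ", ncol(batch@features),
         " != model featureDim ", model$featureDim)
  }
  reps <- vector("list", model$numLayers + 1L)
  reps[[1]] <- batch@features
  for (l in seq_len(model$numLayers)) {
    reps[[l + 1L]] <- ginLayerForward(batch, reps[[l]],
                                      gin_layer_params(model, l), training)
  }
  rG <- graphReadout(batch, reps)
  rv <- nodeConcat(reps)
  gs <- sweep(rG %*% model$par[["graph_head.W"]], 2L,
              as.vector(model$par[["graph_head.b"]]), "+")
  ns <- if (!is.null(model$par[["node_head.W"]])) {
    sweep(rv %*% model$par[["node_head.W"]], 2L,
          as.vector(model$par[["node_head.b"]]), "+")
  } else matrix(0, nrow(rv), 0L)
  new("ModelOutput", nodeScores = ns, graphScores = gs,
      perLayerNodeReps = reps, graphEmbedding = rG, nodeEmbedding = rv)
}

# ---- autodiff path (training) ----------------------------------------------

ad_param_ctx <- function(tape) {
  ctx <- new.env(parent = emptyenv())
  ctx$tape <- tape
  ctx$ids <- list()
  ctx
}

ad_param <- function(ctx, name, value) {
  nd <- ad_leaf(ctx$tape, value, needs = TRUE)
  ctx$ids[[name]] <- nd$id
  nd
}

# Collect named parameter gradients (zeros where unused) after ad_backward.
ad_collect_grads <- function(ctx, grads, par) {
  out <- lapply(names(par), function(nm) {
    id <- ctx$ids[[nm]]
    g <- if (is.null(id)) NULL else grads[[id]]
    if (is.null(g)) array(0, dim(par[[nm]])) else g
  })
  names(out) <- names(par)
  out
}

# AD forward for MT-GIN; returns ad nodes for scores plus the param context.
gin_forward_ad <- function(batch, model, tape, ctx, training) {
  A <- batch@blockAdjacency
  B <- length(batch@graphLabels)
  h <- ad_leaf(tape, batch@features)
  reps <- list(h)
  for (l in seq_len(model$numLayers)) {
    p <- sprintf("gin%d.", l)
    agg <- ad_lmul_const(A, h)
    if (model$trainableEpsilon) {
      epsn <- ad_param(ctx, paste0(p, "eps"), model$par[[paste0(p, "eps")]])
      # (1 + eps) * h: scale rows of h by scalar node
      one_plus <- ad_node(tape, 1 + ad_value(epsn), list(epsn),
                          back = function(g) list(g))
      selfterm <- ad_node(tape, ad_value(h) * as.numeric(ad_value(one_plus)),
                          list(h, one_plus), back = local({
                            hv <- ad_value(h); sc <- as.numeric(ad_value(one_plus))
                            function(g) list(g * sc, matrix(sum(g * hv), 1, 1))
                          }))
      h2 <- ad_add(selfterm, agg)
    } else {
      h2 <- ad_add(ad_scale(h, 1 + model$epsilon), agg)
    }
    W1 <- ad_param(ctx, paste0(p, "W1"), model$par[[paste0(p, "W1")]])
    b1 <- ad_param(ctx, paste0(p, "b1"), model$par[[paste0(p, "b1")]])
    g1 <- ad_param(ctx, paste0(p, "g1"), model$par[[paste0(p, "g1")]])
    be1 <- ad_param(ctx, paste0(p, "be1"), model$par[[paste0(p, "be1")]])
    W2 <- ad_param(ctx, paste0(p, "W2"), model$par[[paste0(p, "W2")]])
    b2 <- ad_param(ctx, paste0(p, "b2"), model$par[[paste0(p, "b2")]])
    g2 <- ad_param(ctx, paste0(p, "g2"), model$par[[paste0(p, "g2")]])
    be2 <- ad_param(ctx, paste0(p, "be2"), model$par[[paste0(p, "be2")]])
    z <- ad_addbias(ad_matmul(h2, W1), b1)
    z <- ad_batchnorm(z, g1, be1, model$bn, paste0(p, "bn1"), training)
    z <- ad_relu(z)
    z <- ad_addbias(ad_matmul(z, W2), b2)
    z <- ad_batchnorm(z, g2, be2, model$bn, paste0(p, "bn2"), training)
    h <- ad_relu(z)
    reps[[l + 1L]] <- h
  }
  readouts <- lapply(reps, function(r) ad_groupsum(r, batch@graphMembership, B))
  rG <- ad_cbind(readouts)
  rv <- ad_cbind(reps)
  gW <- ad_param(ctx, "graph_head.W", model$par[["graph_head.W"]])
  gb <- ad_param(ctx, "graph_head.b", model$par[["graph_head.b"]])
  gs <- ad_addbias(ad_matmul(rG, gW), gb)
  ns <- NULL
  if (!is.null(model$par[["node_head.W"]])) {
    nW <- ad_param(ctx, "node_head.W", model$par[["node_head.W"]])
    nb <- ad_param(ctx, "node_head.b", model$par[["node_head.b"]])
    ns <- ad_addbias(ad_matmul(rv, nW), nb)
  }
  list(graphScores = gs, nodeScores = ns, rG = rG, rv = rv)
}
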