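# Joint loss and the training protocol: masked categorical cross-entropy for
# both tasks, L = L_G + alpha * L_v, Adam with a step-decayed learning rate,
# 10 mini-batch iterations per epoch, and stratified k-fold cross-validation
# reporting per-task accuracies.

#' Masked node-classification cross-entropy
#'
#' Softmax cross-entropy of the node scores against the observed node
#' labels; rows under a FALSE mask are excluded from the sum and the count.
#' `reduction = "mean"` (default) divides by the number of unmasked nodes so
#' the node and graph losses live on comparable scales; `"sum"` is the raw
#' summed negative log-likelihood.
#'
#' @param scores N x C_v matrix of raw scores.
#' @param labels integer vector of 0-based node classes.
#' @param mask logical vector (default: all observed).
#' @param reduction "mean" or "sum".
#' @return Nonnegative scalar; 0 (with a warning) when no node is unmasked.
#' @export
nodeCrossEntropy <- function(scores, labels, mask = NULL,
                             reduction = c("mean", "sum")) {
  reduction <- match.arg(reduction)
  scores <- as.matrix(scores)
  if (is.null(mask)) mask <- rep(TRUE, nrow(scores))
  mask <- as.logical(mask)
  cnt <- sum(mask)
  if (cnt == 0L) {
    warning("no unmasked labels; cross-entropy defined as 0")
    return(0)
  }
  p <- row_softmax(scores)
  ll <- -sum(log(pmax(p[cbind(which(mask), labels[mask] + 1L)], 1e-300)))
  if (reduction == "mean") ll / cnt else ll
}

#' Graph-classification cross-entropy
#'
#' As [nodeCrossEntropy()] with one row per graph and no mask.
#'
#' @param scores B x C_G matrix of raw scores.
#' @param labels integer vector of 0-based graph classes.
#' @param reduction "mean" or "sum".
#' @return Nonnegative scalar.
#' @export
graphCrossEntropy <- function(scores, labels, reduction = c("mean", "sum")) {
  nodeCrossEntropy(scores, labels, mask = NULL, reduction = match.arg(reduction))
}

#' Joint multi-task loss
#'
#' `L = L_G + alpha * L_v`; alpha = 0 recovers the single-task graph
#' classifier.
#'
#' @param lossGraph,lossNode the two task losses.
#' @param alpha nonnegative weight of the node task.
#' @return The combined loss.
#' @export
jointLoss <- function(lossGraph, lossNode, alpha) {
  if (!is.finite(alpha) || alpha < 0) {
    stop("argument error: alpha must be a nonnegative number")
  }
  stopifnot(is.finite(lossGraph), is.finite(lossNode))
  lossGraph + alpha * lossNode
}

#' Training configuration
#'
#' Defaults follow the training protocol the models are evaluated under:
#' 350 epochs of 10 mini-batch iterations each, Adam with initial learning
#' rate 0.01 halved every 50 epochs, batch normalization on, and 10-fold
#' cross-validation. `alphaGrid` records the sweep values for the node-task
#' weight.
#'
#' @param alpha node-task loss weight (>= 0).
#' @param epochs,itersPerEpoch epochs and mini-batches per epoch.
#' @param lr0,lrDecay,lrStep initial learning rate, decay factor, and the
#'   epoch period of the decay.
#' @param folds cross-validation folds.
#' @param seed integer seed controlling initialization, fold assignment and
#'   batch shuffling.
#' @param model "gin" or "diffpool".
#' @param hidden hidden width.
#' @param numLayers GIN message-passing layers.
#' @param clusterRatio DIFFPOOL pooling ratio.
#' @param nodeTap DIFFPOOL node-head tap layer (1 or 2).
#' @param reduction loss reduction, "mean" (default) or "sum".
#' @return A list of class `"TrainConfig"`.
#' @export
trainConfig <- function(alpha = 1, epochs = 350L, itersPerEpoch = 10L,
                        lr0 = 0.01, lrDecay = 0.5, lrStep = 50L, folds = 10L,
                        seed = 1L, model = c("gin", "diffpool"), hidden = 64L,
                        numLayers = 5L, clusterRatio = 0.1, nodeTap = 2L,
                        reduction = c("mean", "sum")) {
  cfg <- list(alpha = alpha, epochs = as.integer(epochs),
              itersPerEpoch = as.integer(itersPerEpoch), lr0 = lr0,
              lrDecay = lrDecay, lrStep = as.integer(lrStep),
              folds = as.integer(folds), seed = as.integer(seed),
              model = match.arg(model), hidden = as.integer(hidden),
              numLayers = as.integer(numLayers), clusterRatio = clusterRatio,
              nodeTap = as.integer(nodeTap),
              reduction = match.arg(reduction),
              alphaGrid = c(0, 0.5, 0.75, 1.25, 1.5, 2))
  if (cfg$alpha < 0) stop("argument error: alpha must be >= 0")
  stopifnot(cfg$epochs >= 1L, cfg$folds >= 2L, cfg$itersPerEpoch >= 1L)
  class(cfg) <- "TrainConfig"
  cfg
}

#' Learning rate at a given epoch
#'
#' Step decay: `lr0 * lrDecay^floor(epoch / lrStep)` with the defaults
#' 0.01 halved every 50 epochs.
#'
#' @param config a [trainConfig()].
#' @param epoch 0-based epoch index in `[0, epochs)`.
#' @return The learning rate.
#' @export
lrAtEpoch <- function(config, epoch) {
  if (any(epoch < 0L | epoch >= config$epochs)) {
    stop("argument error: epoch must lie in [0, ", config$epochs, ")")
  }
  config$lr0 * config$lrDecay^(epoch %/% config$lrStep)
}

# ---- optimizer --------------------------------------------------------------

adam_init <- function(par) {
  list(m = lapply(par, function(p) array(0, dim(p))),
       v = lapply(par, function(p) array(0, dim(p))),
       t = 0L)
}

adam_step <- function(par, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(par)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    par[[nm]] <- par[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(par = par, state = state)
}

# ---- forward dispatch and metrics -------------------------------------------

#' Model forward pass (dispatch on model kind)
#'
#' @param batch a [GraphBatch-class].
#' @param model a [ginModel()] or [diffpoolModel()].
#' @param training batch-statistics mode.
#' @return A [ModelOutput-class].
#' @export
modelForward <- function(batch, model, training = FALSE) {
  switch(model$kind,
         gin = ginForward(batch, model, training),
         diffpool = diffpoolForward(batch, model, training),
         stop("unknown model kind '", model$kind, "'"))
}

graph_accuracy <- function(output, batch) {
  pred <- max.col(graphScores(output), ties.method = "first") - 1L
  mean(pred == batch@graphLabels)
}

node_accuracy <- function(output, batch) {
  if (ncol(nodeScores(output)) == 0L || !any(batch@nodeMask)) return(NA_real_)
  pred <- max.col(nodeScores(output), ties.method = "first") - 1L
  mean(pred[batch@nodeMask] == batch@nodeLabels[batch@nodeMask])
}

#' Joint loss and parameter gradients on a batch
#'
#' Runs the model's differentiable forward pass, forms
#' `L = L_G + alpha * L_v`, and backpropagates, returning the loss value,
#' both components, and the gradient for every parameter. This is the exact
#' quantity one optimizer step consumes; it is also the hook for
#' finite-difference verification.
#'
#' @param batch a [GraphBatch-class].
#' @param model a model object.
#' @param alpha node-task weight.
#' @param training batch-statistics mode (TRUE during optimization). Note
#'   that in training mode batch-normalization running statistics are
#'   updated as a side effect.
#' @param reduction loss reduction ("mean" or "sum").
#' @return list with `loss`, `lossGraph`, `lossNode`, and named `grads`.
#' @export
lossAndGradients <- function(batch, model, alpha = 1, training = TRUE,
                             reduction = "mean") {
  if (alpha < 0) stop("argument error: alpha must be >= 0")
  tape <- ad_tape()
  ctx <- ad_param_ctx(tape)
  out <- switch(model$kind,
                gin = gin_forward_ad(batch, model, tape, ctx, training),
                diffpool = diffpool_forward_ad(batch, model, tape, ctx, training))
  lG <- ad_xent(out$graphScores, batch@graphLabels + 1L,
                rep(TRUE, length(batch@graphLabels)), reduction)
  use_node <- alpha > 0 && !is.null(out$nodeScores) && any(batch@nodeMask)
  if (use_node) {
    lv <- ad_xent(out$nodeScores, batch@nodeLabels + 1L, batch@nodeMask,
                  reduction)
    total <- ad_add(lG, ad_scale(lv, alpha))
  } else {
    lv <- NULL
    total <- lG
  }
  if (!is.finite(ad_value(total)[1])) {
    stop("divergence: non-finite joint loss")
  }
  grads <- ad_backward(total)
  list(loss = ad_value(total)[1],
       lossGraph = ad_value(lG)[1],
       lossNode = if (is.null(lv)) 0 else ad_value(lv)[1],
       grads = ad_collect_grads(ctx, grads, model$par))
}

new_model_for <- function(config, featureDim, numGraphClasses,
                          numNodeClasses, maxNodes, seed) {
  if (config$model == "gin") {
    ginModel(featureDim, numGraphClasses, numNodeClasses,
             numLayers = config$numLayers, hidden = config$hidden, seed = seed)
  } else {
    diffpoolModel(featureDim, numGraphClasses, numNodeClasses,
                  hidden = config$hidden, clusterRatio = config$clusterRatio,
                  maxNodes = maxNodes, nodeTap = config$nodeTap, seed = seed)
  }
}

evaluate_split <- function(model, batch, alpha, reduction) {
  out <- modelForward(batch, model, training = FALSE)
  lG <- graphCrossEntropy(graphScores(out), batch@graphLabels, reduction)
  lv <- if (ncol(nodeScores(out)) > 0L && any(batch@nodeMask)) {
    nodeCrossEntropy(nodeScores(out), batch@nodeLabels, batch@nodeMask,
                     reduction)
  } else 0
  list(lossGraph = lG, lossNode = lv, loss = jointLoss(lG, lv, alpha),
       graphAcc = graph_accuracy(out, batch),
       nodeAcc = node_accuracy(out, batch))
}

#' Train a model on one train/validation split
#'
#' Runs `epochs * itersPerEpoch` Adam steps on shuffled mini-batches of the
#' joint loss (batch size `ceil(|train| / itersPerEpoch)`), records both
#' losses and both accuracies on the training and validation sets after
#' every epoch, and reports final-epoch and best-epoch validation
#' accuracies. Fully reproducible for a fixed `config$seed`.
#'
#' @param train,val [GraphDataset-class] splits with consistent metadata.
#' @param config a [trainConfig()].
#' @param model optionally, a pre-initialized model to continue from.
#' @return list of class `"FoldRecord"`: `model`, per-epoch `trace`
#'   data frame, `final` and `best` validation metrics.
#' @export
trainFold <- function(train, val, config, model = NULL) {
  stopifnot(is(train, "GraphDataset"), is(val, "GraphDataset"))
  if (train@numGraphClasses != val@numGraphClasses ||
      train@featureDim != val@featureDim) {
    stop("argument error: train/val metadata mismatch")
  }
  withr::local_seed(config$seed)
  max_nodes <- max(vapply(c(train@graphs, val@graphs), numNodes, integer(1)))
  if (is.null(model)) {
    model <- new_model_for(config, train@featureDim, train@numGraphClasses,
                           train@numNodeClasses, max_nodes,
                           seed = sample.int(.Machine$integer.max, 1L))
  }
  opt <- adam_init(model$par)
  n <- length(train@graphs)
  bs <- ceiling(n / config$itersPerEpoch)
  train_batch <- batchGraphs(train)
  val_batch <- batchGraphs(val)
  trace <- vector("list", config$epochs)
  for (epoch in seq_len(config$epochs) - 1L) {
    lr <- lrAtEpoch(config, epoch)
    order_ <- sample.int(n)
    for (it in seq_len(config$itersPerEpoch)) {
      lo <- (it - 1L) * bs + 1L
      if (lo > n) next  # fewer graphs than iterations
      hi <- min(it * bs, n)
      batch <- batchGraphs(train@graphs[order_[lo:hi]])
      lg <- lossAndGradients(batch, model, alpha = config$alpha,
                             training = TRUE, reduction = config$reduction)
      upd <- adam_step(model$par, lg$grads, opt, lr)
      model$par <- upd$par
      opt <- upd$state
    }
    tr <- evaluate_split(model, train_batch, config$alpha, config$reduction)
    va <- evaluate_split(model, val_batch, config$alpha, config$reduction)
    trace[[epoch + 1L]] <- data.frame(
      epoch = epoch, lr = lr,
      trainLossGraph = tr$lossGraph, trainLossNode = tr$lossNode,
      trainLoss = tr$loss,
      trainGraphAcc = tr$graphAcc, trainNodeAcc = tr$nodeAcc,
      valLossGraph = va$lossGraph, valLossNode = va$lossNode,
      valLoss = va$loss,
      valGraphAcc = va$graphAcc, valNodeAcc = va$nodeAcc)
  }
  trace <- do.call(rbind, trace)
  best_i <- which.max(trace$valGraphAcc)
  structure(list(
    model = model,
    trace = trace,
    final = trace[nrow(trace), c("valGraphAcc", "valNodeAcc")],
    best = trace[best_i, c("epoch", "valGraphAcc", "valNodeAcc")]),
    class = "FoldRecord")
}

# Deterministic stratified fold assignment keyed by graphId: graphs are
# sorted by id within each class before the seeded shuffle, so reordering
# the dataset does not change fold membership.
stratified_folds <- function(dataset, folds, seed) {
  labels <- vapply(dataset@graphs, graphLabel, integer(1))
  ids <- vapply(dataset@graphs, function(g) g@graphId, character(1))
  assign <- integer(length(labels))
  withr::local_seed(seed)
  pos <- 0L  # rotate the round-robin across classes so fold sizes stay even
  for (cl in sort(unique(labels))) {
    idx <- which(labels == cl)
    idx <- idx[order(ids[idx])]
    idx <- idx[sample.int(length(idx))]
    assign[idx] <- (pos + seq_along(idx) - 1L) %% folds + 1L
    pos <- pos + length(idx)
  }
  assign
}

#' Stratified k-fold cross-validation
#'
#' Assigns graphs to folds stratified by graph label (deterministically from
#' the seed, keyed by graph id), trains one model per fold with
#' [trainFold()], and aggregates validation accuracies for both tasks
#' (final-epoch and best-epoch).
#'
#' @param dataset a [GraphDataset-class] with at least `folds` graphs.
#' @param config a [trainConfig()].
#' @param logDir optional directory; per-fold loss traces and the summary
#'   are written there as tab-separated text.
#' @return list of class `"CVReport"`: `folds` (per-fold summary data
#'   frame), `traces`, `meanGraphAcc`, `sdGraphAcc`, `meanNodeAcc`,
#'   `sdNodeAcc` (best-epoch figures), and the final-epoch counterparts.
#' @export
crossValidate <- function(dataset, config, logDir = NULL) {
  stopifnot(is(dataset, "GraphDataset"))
  if (length(dataset@graphs) < config$folds) {
    stop("argument error: dataset smaller than the number of folds")
  }
  assign <- stratified_folds(dataset, config$folds, config$seed)
  labels <- vapply(dataset@graphs, graphLabel, integer(1))
  rows <- vector("list", config$folds)
  traces <- vector("list", config$folds)
  for (k in seq_len(config$folds)) {
    tr_idx <- which(assign != k)
    va_idx <- which(assign == k)
    missing_cl <- setdiff(unique(labels), unique(labels[tr_idx]))
    if (length(missing_cl)) {
      warning("fold ", k, ": class(es) ", paste(missing_cl, collapse = ", "),
              " absent from the training split")
    }
    tr <- methods::initialize(dataset, graphs = dataset@graphs[tr_idx])
    va <- methods::initialize(dataset, graphs = dataset@graphs[va_idx])
    fold_cfg <- config
    fold_cfg$seed <- config$seed + k
    rec <- trainFold(tr, va, fold_cfg)
    rows[[k]] <- data.frame(
      fold = k, valSize = length(va_idx),
      finalGraphAcc = rec$final$valGraphAcc,
      finalNodeAcc = rec$final$valNodeAcc,
      bestEpoch = rec$best$epoch,
      bestGraphAcc = rec$best$valGraphAcc,
      bestNodeAcc = rec$best$valNodeAcc)
    traces[[k]] <- rec$trace
  }
  folds_df <- do.call(rbind, rows)
  rep <- structure(list(
    folds = folds_df, traces = traces, config = config,
    meanGraphAcc = mean(folds_df$bestGraphAcc),
    sdGraphAcc = stats::sd(folds_df$bestGraphAcc),
    meanNodeAcc = mean(folds_df$bestNodeAcc),
    sdNodeAcc = stats::sd(folds_df$bestNodeAcc),
    meanFinalGraphAcc = mean(folds_df$finalGraphAcc),
    meanFinalNodeAcc = mean(folds_df$finalNodeAcc)),
    class = "CVReport")
  if (!is.null(logDir)) {
    if (!dir.exists(logDir)) dir.create(logDir, recursive = TRUE)
    utils::write.table(folds_df, file.path(logDir, "cv_summary.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    for (k in seq_along(traces)) {
      utils::write.table(traces[[k]],
                         file.path(logDir, sprintf("fold%02d_trace.tsv", k)),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    }
  }
  rep
}

#' @export
print.CVReport <- function(x, ...) {
  cat(sprintf("CVReport (%s, alpha=%g, %d folds)\n", x$config$model,
              x$config$alpha, x$config$folds))
  cat(sprintf("  graph accuracy (best epoch): %.4f +/- %.4f\n",
              x$meanGraphAcc, x$sdGraphAcc))
  cat(sprintf("  node  accuracy (best epoch): %.4f +/- %.4f\n",
              x$meanNodeAcc, x$sdNodeAcc))
  invisible(x)
}
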