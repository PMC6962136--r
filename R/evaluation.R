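# Embedding export and 2-D visualization. Graph representations r_G and node
# representations r_v are extracted in evaluation mode (fixed normalization
# statistics) and can be projected to the plane with an exact t-SNE
# (pairwise affinities with perplexity calibration, early exaggeration,
# momentum gradient descent) for cluster inspection.

#' Extract graph and node embeddings from a model
#'
#' Runs the forward pass in evaluation mode and returns the graph
#' representation matrix (r_G: the concatenated per-layer sum readout for
#' GIN, the pre-head cluster readout for DIFFPOOL) and the node
#' representation matrix (r_v: the per-layer concatenation for GIN, the
#' pre-pool tap for DIFFPOOL), together with their labels. Repeated calls
#' with the same inputs are bit-identical.
#'
#' @param dataset a [GraphDataset-class].
#' @param model a trained (or freshly initialized) model.
#' @return list of class `"EmbeddingExport"`: `graphEmbeddings`,
#'   `graphLabels`, `graphIds`, `nodeEmbeddings`, `nodeLabels`, `nodeMask`,
#'   `nodeGraph` (source graph index per node).
#' @export
extractEmbeddings <- function(dataset, model) {
  batch <- batchGraphs(dataset)
  out <- modelForward(batch, model, training = FALSE)
  structure(list(
    graphEmbeddings = graphEmbedding(out),
    graphLabels = batch@graphLabels,
    graphIds = batch@graphIds,
    nodeEmbeddings = nodeEmbedding(out),
    nodeLabels = batch@nodeLabels,
    nodeMask = batch@nodeMask,
    nodeGraph = batch@graphMembership), class = "EmbeddingExport")
}

#' Write an embedding export as delimited text
#'
#' @param export an [extractEmbeddings()] result.
#' @param file output path (tab-separated, one-line header); node rows carry
#'   their label and source graph, graph rows their label and id.
#' @param what "graphs" or "nodes".
#' @return Invisibly, the file path.
#' @export
writeEmbeddings <- function(export, file, what = c("graphs", "nodes")) {
  what <- match.arg(what)
  if (what == "graphs") {
    df <- data.frame(id = export$graphIds, label = export$graphLabels,
                     export$graphEmbeddings)
  } else {
    df <- data.frame(graph = export$nodeGraph, label = export$nodeLabels,
                     observed = export$nodeMask, export$nodeEmbeddings)
  }
  utils::write.table(df, file, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(file)
}

# entropy/probability row for one point at precision beta
tsne_row <- function(d2, beta) {
  p <- exp(-d2 * beta)
  s <- sum(p)
  if (s < 1e-300) p[] <- 1 / length(p) else p <- p / s
  h <- -sum(p[p > 0] * log(p[p > 0]))
  list(p = p, h = h)
}

#' Project embeddings to 2-D with t-SNE
#'
#' Exact (quadratic-cost) t-SNE: per-point Gaussian affinities calibrated to
#' the target perplexity by bisection, symmetrized, then minimized against
#' the Student-t low-dimensional affinities by momentum gradient descent
#' with early exaggeration and per-coordinate gains. Deterministic for a
#' fixed seed. When there are too few points for the requested perplexity,
#' the perplexity is shrunk with a warning.
#'
#' @param embeddings numeric matrix with at least 2 rows.
#' @param seed integer seed for the initial layout.
#' @param perplexity target perplexity (default 30).
#' @param iters gradient-descent iterations (default 1000).
#' @param learningRate step size; the default `NULL` scales it with the
#'   point count (`max(n/12, 2)`), which keeps the early exaggerated
#'   attraction stable for small inputs (t-SNE gradients scale like 1/n).
#' @return rows x 2 coordinate matrix.
#' @export
project2d <- function(embeddings, seed = 1L, perplexity = 30,
                      iters = 1000L, learningRate = NULL) {
  x <- as.matrix(embeddings)
  n <- nrow(x)
  if (n < 2L) stop("argument error: need at least 2 rows to project")
  if (is.null(learningRate)) learningRate <- max(n / 12, 2)
  if (3 * perplexity + 1 > n) {
    perplexity <- max(1, (n - 1) / 3)
    warning("perplexity shrunk to ", format(perplexity), " for ", n, " points")
  }
  sq <- rowSums(x^2)
  d2 <- pmax(outer(sq, sq, "+") - 2 * tcrossprod(x), 0)
  target <- log(perplexity)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    di <- d2[i, -i]
    beta <- 1
    lo <- -Inf; hi <- Inf
    for (it in 1:50) {
      r <- tsne_row(di, beta)
      if (abs(r$h - target) < 1e-5) break
      if (r$h > target) {        # too flat: increase beta
        lo <- beta
        beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2
      } else {
        hi <- beta
        beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2
      }
    }
    P[i, -i] <- tsne_row(di, beta)$p
  }
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, 1e-12)

  withr::local_seed(seed)
  y <- matrix(stats::rnorm(n * 2, sd = 1e-4), n, 2)
  inc <- matrix(0, n, 2)
  gains <- matrix(1, n, 2)
  momentum <- 0.5
  for (it in seq_len(iters)) {
    ex <- if (it <= 100L) 4 else 1      # early exaggeration
    ysq <- rowSums(y^2)
    num <- 1 / (1 + pmax(outer(ysq, ysq, "+") - 2 * tcrossprod(y), 0))
    diag(num) <- 0
    Q <- pmax(num / sum(num), 1e-12)
    W <- (ex * P - Q) * num
    grad <- 4 * (diag(rowSums(W)) - W) %*% y
    gains <- pmax(ifelse(sign(grad) != sign(inc), gains + 0.2, gains * 0.8), 0.01)
    inc <- momentum * inc - learningRate * gains * grad
    y <- y + inc
    y <- sweep(y, 2L, colMeans(y))
    if (it == 250L) momentum <- 0.8
  }
  y
}

#' Tabulate dataset statistics
#'
#' One row per dataset with the [datasetStats()] fields, printed at
#' benchmark-table precision (two decimals on the averages).
#'
#' @param datasets list of [GraphDataset-class] objects.
#' @return data.frame (empty for an empty list).
#' @export
reportStats <- function(datasets) {
  if (!length(datasets)) {
    return(data.frame(name = character(), numGraphs = integer(),
                      avgNodes = numeric(), avgEdges = numeric(),
                      numGraphClasses = integer(), numNodeClasses = integer(),
                      attrDim = integer()))
  }
  rows <- lapply(datasets, function(d) {
    s <- datasetStats(d)
    data.frame(name = s$name, numGraphs = s$numGraphs,
               avgNodes = round(s$avgNodes, 2), avgEdges = round(s$avgEdges, 2),
               numGraphClasses = s$numGraphClasses,
               numNodeClasses = s$numNodeClasses, attrDim = s$attrDim)
  })
  do.call(rbind, rows)
}
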