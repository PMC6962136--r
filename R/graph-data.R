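#' Use zero-padded adjacency rows as node features
#'
#' For datasets whose nodes carry no attribute vectors, each node's feature
#' vector is set to its row of the graph adjacency matrix, right-padded with
#' zeros to a common width so every graph shares one feature dimension.
#'
#' @param dataset a [GraphDataset-class].
#' @param padTo target feature width; defaults to the dataset-wide maximum
#'   node count (the minimal width that fits every graph). Must be at least
#'   the largest node count.
#' @return The dataset with `featureDim = padTo` and rebuilt features.
#' @examples
#' g <- LabeledGraph(matrix(c(0, 1, 1, 0), 2))
#' d <- buildAdjacencyFeatures(GraphDataset(list(g)), padTo = 4)
#' nodeFeatures(d[[1]])
#' @export
buildAdjacencyFeatures <- function(dataset, padTo = NULL) {
  stopifnot(is(dataset, "GraphDataset"))
  sizes <- vapply(dataset@graphs, numNodes, integer(1))
  nmax <- max(sizes)
  if (is.null(padTo)) padTo <- nmax
  padTo <- as.integer(padTo)
  if (padTo < nmax) {
    stop("dimension error: padTo (", padTo,
         ") is smaller than the largest graph (", nmax, " nodes)")
  }
  dataset@graphs <- lapply(dataset@graphs, function(g) {
    n <- numNodes(g)
    f <- matrix(0, n, padTo)
    if (n > 0L) f[, seq_len(n)] <- g@adjacency
    g@nodeFeatures <- f
    g
  })
  dataset@featureDim <- padTo
  attr(dataset, "adjacencyFeatures") <- TRUE
  dataset
}

#' Pack graphs into one block-diagonal batch
#'
#' Stacks a list of graphs into a single sparse block-diagonal adjacency with
#' concatenated feature rows and a node-to-graph membership vector, the form
#' the model forward passes consume. Unbatching ([unbatchGraphs()]) recovers
#' the inputs exactly.
#'
#' @param graphs non-empty list of [LabeledGraph-class] with a common feature
#'   dimension, or a [GraphDataset-class].
#' @return A [GraphBatch-class].
#' @export
batchGraphs <- function(graphs) {
  if (is(graphs, "GraphDataset")) graphs <- graphs@graphs
  if (!length(graphs)) stop("argument error: empty graph list")
  d <- ncol(graphs[[1]]@nodeFeatures)
  if (any(vapply(graphs, function(g) ncol(g@nodeFeatures), integer(1)) != d)) {
    stop("argument error: graphs do not share a feature dimension")
  }
  sizes <- vapply(graphs, numNodes, integer(1))
  offsets <- cumsum(c(0L, sizes[-length(sizes)]))
  N <- sum(sizes)
  ii <- integer(); jj <- integer()
  for (k in seq_along(graphs)) {
    e <- which(graphs[[k]]@adjacency != 0, arr.ind = TRUE)
    if (nrow(e)) {
      ii <- c(ii, e[, 1] + offsets[k])
      jj <- c(jj, e[, 2] + offsets[k])
    }
  }
  block <- Matrix::sparseMatrix(i = ii, j = jj, x = 1, dims = c(N, N))
  new("GraphBatch",
      blockAdjacency = block,
      features = do.call(rbind, lapply(graphs, nodeFeatures)),
      nodeLabels = unlist(lapply(graphs, nodeLabels)),
      nodeMask = unlist(lapply(graphs, function(g) g@nodeLabelMask)),
      graphMembership = rep(seq_along(graphs), sizes),
      graphLabels = vapply(graphs, graphLabel, integer(1)),
      graphIds = vapply(graphs, function(g) g@graphId, character(1)))
}

#' Recover the individual graphs from a batch
#'
#' @param batch a [GraphBatch-class].
#' @return List of [LabeledGraph-class] in batch order.
#' @export
unbatchGraphs <- function(batch) {
  stopifnot(is(batch, "GraphBatch"))
  B <- length(batch@graphLabels)
  a_dense <- as.matrix(batch@blockAdjacency)
  lapply(seq_len(B), function(k) {
    idx <- which(batch@graphMembership == k)
    LabeledGraph(
      adjacency = a_dense[idx, idx, drop = FALSE],
      nodeFeatures = batch@features[idx, , drop = FALSE],
      nodeLabels = batch@nodeLabels[idx],
      nodeLabelMask = batch@nodeMask[idx],
      graphLabel = batch@graphLabels[k],
      graphId = batch@graphIds[k])
  })
}

#' Summary statistics of a graph dataset
#'
#' The usual benchmark summary: graph count, average node and undirected edge
#' counts (each undirected edge counted once), class counts, and the
#' continuous-attribute dimension when the dataset carries attributes.
#'
#' @param dataset a [GraphDataset-class].
#' @return A list of class `"DatasetStats"` with fields `numGraphs`,
#'   `avgNodes`, `avgEdges`, `numGraphClasses`, `numNodeClasses`, `attrDim`
#'   (NA when features are not continuous attributes).
#' @export
datasetStats <- function(dataset) {
  stopifnot(is(dataset, "GraphDataset"))
  sizes <- vapply(dataset@graphs, numNodes, integer(1))
  edges <- vapply(dataset@graphs, function(g) sum(g@adjacency) / 2, numeric(1))
  structure(list(
    name = dataset@name,
    numGraphs = length(dataset@graphs),
    avgNodes = mean(sizes),
    avgEdges = mean(edges),
    numGraphClasses = dataset@numGraphClasses,
    numNodeClasses = dataset@numNodeClasses,
    attrDim = if (is.null(attr(dataset, "attrDim"))) NA_integer_
              else as.integer(attr(dataset, "attrDim"))
  ), class = "DatasetStats")
}

#' @export
print.DatasetStats <- function(x, ...) {
  cat(sprintf("%s: %d graphs | avg nodes %.2f | avg edges %.2f | C_G=%d | C_v=%d | attr dim %s\n",
              x$name, x$numGraphs, x$avgNodes, x$avgEdges,
              x$numGraphClasses, x$numNodeClasses,
              ifelse(is.na(x$attrDim), "-", x$attrDim)))
  invisible(x)
}
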