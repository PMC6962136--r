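#' @import methods
#' @importFrom Matrix Matrix bdiag nnzero
#' @importClassesFrom Matrix Matrix
#' @importFrom stats runif rnorm sd
#' @importFrom utils read.table write.table
NULL

#' A single labeled graph
#'
#' One undirected graph with a binary adjacency matrix (zero diagonal), a
#' node feature matrix, per-node integer class labels with an observation
#' mask, and one graph-level class label. Labels are 0-based and contiguous
#' within a dataset; `nodeLabelMask` marks which node labels are observed so
#' datasets without node labels can still be trained with the node task
#' switched off (loss weight alpha = 0).
#'
#' @slot adjacency n x n binary symmetric matrix, zero diagonal.
#' @slot nodeFeatures n x d numeric matrix (may have 0 columns before
#'   feature construction).
#' @slot nodeLabels integer vector of length n, values in `[0, C_v)`;
#'   entries under a FALSE mask are ignored.
#' @slot nodeLabelMask logical vector of length n; TRUE = label observed.
#' @slot graphLabel integer scalar in `[0, C_G)`.
#' @slot graphId character scalar identifier.
#'
#' @export
setClass("LabeledGraph", representation(
  adjacency = "matrix",
  nodeFeatures = "matrix",
  nodeLabels = "integer",
  nodeLabelMask = "logical",
  graphLabel = "integer",
  graphId = "character"
))

setValidity("LabeledGraph", function(object) {
  a <- object@adjacency
  n <- nrow(a)
  msgs <- character()
  if (ncol(a) != n) msgs <- c(msgs, "adjacency must be square")
  else {
    if (!all(a %in% c(0, 1))) msgs <- c(msgs, "adjacency entries must be 0/1")
    if (n > 0 && any(diag(a) != 0)) msgs <- c(msgs, "adjacency must have zero diagonal")
    if (!isTRUE(all.equal(a, t(a)))) msgs <- c(msgs, "adjacency must be symmetric")
  }
  if (nrow(object@nodeFeatures) != n)
    msgs <- c(msgs, "nodeFeatures must have one row per node")
  if (length(object@nodeLabels) != n)
    msgs <- c(msgs, "nodeLabels must have length n")
  if (length(object@nodeLabelMask) != n)
    msgs <- c(msgs, "nodeLabelMask must have length n")
  obs <- object@nodeLabels[object@nodeLabelMask]
  if (length(obs) && any(is.na(obs) | obs < 0L))
    msgs <- c(msgs, "observed node labels must be non-negative integers")
  if (length(object@graphLabel) != 1L || is.na(object@graphLabel) ||
      object@graphLabel < 0L)
    msgs <- c(msgs, "graphLabel must be a single non-negative integer")
  if (length(msgs)) msgs else TRUE
})

#' Construct a LabeledGraph
#'
#' @param adjacency square binary symmetric matrix (zero diagonal).
#' @param nodeFeatures optional n x d matrix; defaults to a 0-column matrix.
#' @param nodeLabels optional integer vector (0-based classes); unlabeled
#'   graphs get all-zero labels under an all-FALSE mask.
#' @param nodeLabelMask optional logical vector; defaults to TRUE wherever
#'   `nodeLabels` was supplied.
#' @param graphLabel integer graph class (0-based).
#' @param graphId identifier string.
#' @return A [LabeledGraph-class] object.
#' @export
LabeledGraph <- function(adjacency, nodeFeatures = NULL, nodeLabels = NULL,
                         nodeLabelMask = NULL, graphLabel = 0L,
                         graphId = "g") {
  adjacency <- as.matrix(adjacency)
  storage.mode(adjacency) <- "double"
  n <- nrow(adjacency)
  if (is.null(nodeFeatures)) nodeFeatures <- matrix(0, n, 0L)
  nodeFeatures <- as.matrix(nodeFeatures)
  storage.mode(nodeFeatures) <- "double"
  if (is.null(nodeLabels)) {
    nodeLabels <- integer(n)
    if (is.null(nodeLabelMask)) nodeLabelMask <- rep(FALSE, n)
  } else if (is.null(nodeLabelMask)) {
    nodeLabelMask <- rep(TRUE, n)
  }
  new("LabeledGraph",
      adjacency = adjacency, nodeFeatures = nodeFeatures,
      nodeLabels = as.integer(nodeLabels),
      nodeLabelMask = as.logical(nodeLabelMask),
      graphLabel = as.integer(graphLabel), graphId = as.character(graphId))
}

#' A collection of labeled graphs
#'
#' An ordered set of [LabeledGraph-class] objects sharing one feature space
#' and two label spaces (graph classes and node classes). This is the unit
#' the loaders produce, the synthetic generator emits, and the trainers
#' consume.
#'
#' @slot graphs list of LabeledGraph.
#' @slot numGraphClasses number of graph classes C_G.
#' @slot numNodeClasses number of node classes C_v (0 when no node labels).
#' @slot featureDim shared feature dimension d.
#' @slot name dataset name.
#' @export
setClass("GraphDataset", representation(
  graphs = "list",
  numGraphClasses = "integer",
  numNodeClasses = "integer",
  featureDim = "integer",
  name = "character"
))

setValidity("GraphDataset", function(object) {
  msgs <- character()
  for (g in object@graphs) {
    if (!is(g, "LabeledGraph")) return("graphs must all be LabeledGraph")
    if (ncol(g@nodeFeatures) != object@featureDim)
      msgs <- c(msgs, "all graphs must share featureDim")
    if (g@graphLabel >= object@numGraphClasses)
      msgs <- c(msgs, "graphLabel out of range")
    obs <- g@nodeLabels[g@nodeLabelMask]
    if (length(obs) && any(obs >= object@numNodeClasses))
      msgs <- c(msgs, "observed node label out of range")
  }
  if (length(msgs)) unique(msgs) else TRUE
})

#' Construct a GraphDataset
#'
#' Class counts and the feature dimension default to values derived from the
#' graphs themselves (distinct observed labels, assumed contiguous 0-based).
#'
#' @param graphs list of [LabeledGraph-class].
#' @param numGraphClasses,numNodeClasses optional class counts.
#' @param name dataset name.
#' @return A [GraphDataset-class].
#' @export
GraphDataset <- function(graphs, numGraphClasses = NULL,
                         numNodeClasses = NULL, name = "dataset") {
  stopifnot(length(graphs) > 0L)
  if (is.null(numGraphClasses)) {
    numGraphClasses <- max(vapply(graphs, function(g) g@graphLabel, integer(1))) + 1L
  }
  if (is.null(numNodeClasses)) {
    obs <- unlist(lapply(graphs, function(g) g@nodeLabels[g@nodeLabelMask]))
    numNodeClasses <- if (length(obs)) max(obs) + 1L else 0L
  }
  new("GraphDataset", graphs = graphs,
      numGraphClasses = as.integer(numGraphClasses),
      numNodeClasses = as.integer(numNodeClasses),
      featureDim = ncol(graphs[[1]]@nodeFeatures),
      name = as.character(name))
}

#' A block-diagonal batch of graphs
#'
#' Several graphs packed into one sparse block-diagonal adjacency with
#' stacked feature rows and a node-to-graph membership map, so one pass of
#' message passing processes the whole batch without cross-graph edges.
#'
#' @slot blockAdjacency N x N sparse adjacency (Matrix::dgCMatrix).
#' @slot features N x d feature matrix.
#' @slot nodeLabels,nodeMask per-node labels and observation mask.
#' @slot graphMembership integer in 1..B mapping nodes to batch positions.
#' @slot graphLabels length-B graph labels (0-based).
#' @slot graphIds length-B identifiers.
#' @export
setClass("GraphBatch", representation(
  blockAdjacency = "Matrix",
  features = "matrix",
  nodeLabels = "integer",
  nodeMask = "logical",
  graphMembership = "integer",
  graphLabels = "integer",
  graphIds = "character"
))

setValidity("GraphBatch", function(object) {
  N <- nrow(object@blockAdjacency)
  msgs <- character()
  if (nrow(object@features) != N) msgs <- c(msgs, "features row count != N")
  if (length(object@graphMembership) != N)
    msgs <- c(msgs, "graphMembership length != N")
  if (length(object@graphLabels) != length(object@graphIds))
    msgs <- c(msgs, "graphLabels/graphIds length mismatch")
  # no cross-graph edges
  tr <- Matrix::summary(methods::as(object@blockAdjacency, "TsparseMatrix"))
  if (nrow(tr) &&
      any(object@graphMembership[tr$i] != object@graphMembership[tr$j]))
    msgs <- c(msgs, "blockAdjacency links nodes from different graphs")
  if (length(msgs)) msgs else TRUE
})

#' Model forward-pass output
#'
#' Raw (pre-softmax) class scores for both tasks plus the intermediate
#' representations the readouts are built from: per-layer node matrices, the
#' concatenated graph embedding r_G and the concatenated node embedding r_v.
#'
#' @slot nodeScores N x C_v matrix of node-class scores.
#' @slot graphScores B x C_G matrix of graph-class scores.
#' @slot perLayerNodeReps list of N x w_l matrices, layer 0 = raw features.
#' @slot graphEmbedding B x D graph representation r_G.
#' @slot nodeEmbedding N x D' node representation r_v.
#' @export
setClass("ModelOutput", representation(
  nodeScores = "matrix",
  graphScores = "matrix",
  perLayerNodeReps = "list",
  graphEmbedding = "matrix",
  nodeEmbedding = "matrix"
))

# ---- accessors --------------------------------------------------------------

#' @describeIn LabeledGraph-class adjacency matrix accessor
#' @param object a LabeledGraph
#' @export
setGeneric("adjacency", function(object) standardGeneric("adjacency"))
#' @rdname LabeledGraph-class
#' @export
setMethod("adjacency", "LabeledGraph", function(object) object@adjacency)

#' @export
setGeneric("nodeFeatures", function(object) standardGeneric("nodeFeatures"))
#' @rdname LabeledGraph-class
#' @export
setMethod("nodeFeatures", "LabeledGraph", function(object) object@nodeFeatures)

#' @export
setGeneric("nodeLabels", function(object) standardGeneric("nodeLabels"))
#' @rdname LabeledGraph-class
#' @export
setMethod("nodeLabels", "LabeledGraph", function(object) object@nodeLabels)
#' @rdname GraphBatch-class
#' @param object a GraphBatch
#' @export
setMethod("nodeLabels", "GraphBatch", function(object) object@nodeLabels)

#' @export
setGeneric("graphLabel", function(object) standardGeneric("graphLabel"))
#' @rdname LabeledGraph-class
#' @export
setMethod("graphLabel", "LabeledGraph", function(object) object@graphLabel)

#' @export
setGeneric("numNodes", function(object) standardGeneric("numNodes"))
#' @rdname LabeledGraph-class
#' @export
setMethod("numNodes", "LabeledGraph", function(object) nrow(object@adjacency))

#' @export
setGeneric("numGraphs", function(object) standardGeneric("numGraphs"))
#' @rdname GraphDataset-class
#' @param object a GraphDataset
#' @export
setMethod("numGraphs", "GraphDataset", function(object) length(object@graphs))
#' @rdname GraphBatch-class
#' @export
setMethod("numGraphs", "GraphBatch", function(object) length(object@graphLabels))

#' @export
setGeneric("graphs", function(object) standardGeneric("graphs"))
#' @rdname GraphDataset-class
#' @export
setMethod("graphs", "GraphDataset", function(object) object@graphs)

#' Extract one graph from a dataset
#' @param x a GraphDataset
#' @param i graph index
#' @param j,... unused
#' @export
setMethod("[[", "GraphDataset", function(x, i, j, ...) x@graphs[[i]])

#' @export
setGeneric("featureDim", function(object) standardGeneric("featureDim"))
#' @rdname GraphDataset-class
#' @export
setMethod("featureDim", "GraphDataset", function(object) object@featureDim)

#' @export
setGeneric("numGraphClasses", function(object) standardGeneric("numGraphClasses"))
#' @rdname GraphDataset-class
#' @export
setMethod("numGraphClasses", "GraphDataset", function(object) object@numGraphClasses)

#' @export
setGeneric("numNodeClasses", function(object) standardGeneric("numNodeClasses"))
#' @rdname GraphDataset-class
#' @export
setMethod("numNodeClasses", "GraphDataset", function(object) object@numNodeClasses)

setMethod("show", "LabeledGraph", function(object) {
  cat(sprintf("LabeledGraph '%s': %d nodes, %d edges, graph class %d\n",
              object@graphId, nrow(object@adjacency),
              sum(object@adjacency) / 2, object@graphLabel))
})

setMethod("show", "GraphDataset", function(object) {
  s <- datasetStats(object)
  cat(sprintf(
    "GraphDataset '%s': %d graphs | avg nodes %.2f | avg edges %.2f | %d graph classes | %d node classes | d=%d\n",
    object@name, s$numGraphs, s$avgNodes, s$avgEdges,
    object@numGraphClasses, object@numNodeClasses, object@featureDim))
})

setMethod("show", "GraphBatch", function(object) {
  cat(sprintf("GraphBatch: %d graphs, %d nodes, %d directed edges\n",
              length(object@graphLabels), nrow(object@features),
              Matrix::nnzero(object@blockAdjacency)))
})

setMethod("show", "ModelOutput", function(object) {
  cat(sprintf("ModelOutput: %d graphs x %d classes; %d nodes x %d classes; r_G width %d, r_v width %d\n",
              nrow(object@graphScores), ncol(object@graphScores),
              nrow(object@nodeScores), ncol(object@nodeScores),
              ncol(object@graphEmbedding), ncol(object@nodeEmbedding)))
})

#' @describeIn ModelOutput-class node-class score matrix
#' @param object a ModelOutput
#' @export
setGeneric("nodeScores", function(object) standardGeneric("nodeScores"))
#' @rdname ModelOutput-class
#' @export
setMethod("nodeScores", "ModelOutput", function(object) object@nodeScores)

#' @export
setGeneric("graphScores", function(object) standardGeneric("graphScores"))
#' @rdname ModelOutput-class
#' @export
setMethod("graphScores", "ModelOutput", function(object) object@graphScores)

#' @export
setGeneric("graphEmbedding", function(object) standardGeneric("graphEmbedding"))
#' @rdname ModelOutput-class
#' @export
setMethod("graphEmbedding", "ModelOutput", function(object) object@graphEmbedding)

#' @export
setGeneric("nodeEmbedding", function(object) standardGeneric("nodeEmbedding"))
#' @rdname ModelOutput-class
#' @export
setMethod("nodeEmbedding", "ModelOutput", function(object) object@nodeEmbedding)
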