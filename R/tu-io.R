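# Reader/writer for the TU Dortmund graph-kernel benchmark layout:
#   <name>_A.txt               comma-separated edge pairs, 1-based global ids
#   <name>_graph_indicator.txt graph id (1-based) of every node
#   <name>_graph_labels.txt    one label per graph
#   <name>_node_labels.txt     (optional) one discrete label per node
#   <name>_node_attributes.txt (optional) comma-separated floats per node
# Some distributions list each undirected edge once, others twice; the reader
# symmetrizes and deduplicates either way, and the writer always emits both
# directions. All labels are re-indexed to contiguous 0-based integers; the
# original -> internal maps are attached as attr(dataset, "labelMaps").

tu_path <- function(directory, name, suffix) {
  file.path(directory, paste0(name, "_", suffix, ".txt"))
}

read_int_column <- function(path) {
  as.integer(scan(path, what = numeric(), quiet = TRUE, sep = ","))
}

#' Read a dataset in TU Dortmund benchmark format
#'
#' Parses the standard TU file layout into a [GraphDataset-class]. Edge lists
#' are symmetrized and deduplicated, self-loops are dropped with a warning,
#' and graph/node labels are re-indexed to contiguous 0-based integers
#' (original values recoverable through `attr(dataset, "labelMaps")`). When a
#' node-attribute file is present (and `useAttributes = TRUE`) it supplies the
#' node features; otherwise each node's feature vector is its zero-padded
#' adjacency row (see [buildAdjacencyFeatures()]).
#'
#' @param directory directory containing the files.
#' @param name dataset name (file prefix).
#' @param useAttributes use `<name>_node_attributes.txt` as features when
#'   present.
#' @return A [GraphDataset-class].
#' @examples
#' d <- generateDataset(synthConfig(numGraphs = 4, seed = 1))
#' dir <- tempfile(); dir.create(dir)
#' writeTuDataset(d, dir)
#' d2 <- readTuDataset(dir, "synth")
#' numGraphs(d2)
#' @export
readTuDataset <- function(directory, name, useAttributes = TRUE) {
  f_a <- tu_path(directory, name, "A")
  f_ind <- tu_path(directory, name, "graph_indicator")
  f_gl <- tu_path(directory, name, "graph_labels")
  for (f in c(f_a, f_ind, f_gl)) {
    if (!file.exists(f)) {
      stop("TU format error: missing mandatory file '", basename(f), "'")
    }
  }
  ind <- read_int_column(f_ind)
  n_total <- length(ind)
  if (is.unsorted(ind)) {
    stop("TU integrity error: graph_indicator must be non-decreasing")
  }
  graph_ids <- sort(unique(ind))
  n_graphs <- length(graph_ids)

  edges <- utils::read.table(f_a, sep = ",", strip.white = TRUE,
                             col.names = c("i", "j"),
                             colClasses = "integer")
  if (nrow(edges)) {
    if (any(edges$i < 1L | edges$i > n_total | edges$j < 1L | edges$j > n_total)) {
      stop("TU integrity error: node index outside 1..", n_total, " in edge list")
    }
    if (any(ind[edges$i] != ind[edges$j])) {
      stop("TU integrity error: edge connects nodes of different graphs")
    }
    loops <- edges$i == edges$j
    if (any(loops)) {
      warning(sum(loops), " self-loop(s) dropped from '", name, "'")
      edges <- edges[!loops, , drop = FALSE]
    }
  }

  gl_raw <- read_int_column(f_gl)
  if (length(gl_raw) != n_graphs) {
    stop("TU integrity error: graph_labels has ", length(gl_raw),
         " entries for ", n_graphs, " graphs")
  }
  gl_levels <- sort(unique(gl_raw))
  gl <- match(gl_raw, gl_levels) - 1L

  f_nl <- tu_path(directory, name, "node_labels")
  has_node_labels <- file.exists(f_nl)
  if (has_node_labels) {
    nl_raw <- read_int_column(f_nl)
    if (length(nl_raw) != n_total) {
      stop("TU integrity error: node_labels has ", length(nl_raw),
           " entries for ", n_total, " nodes")
    }
    nl_levels <- sort(unique(nl_raw))
    nl <- match(nl_raw, nl_levels) - 1L
  } else {
    nl_levels <- integer()
    nl <- integer(n_total)
  }

  f_na <- tu_path(directory, name, "node_attributes")
  attrs <- NULL
  if (file.exists(f_na) && useAttributes) {
    attrs <- as.matrix(utils::read.table(f_na, sep = ",", strip.white = TRUE))
    dimnames(attrs) <- NULL
    storage.mode(attrs) <- "double"
    if (nrow(attrs) != n_total) {
      stop("TU integrity error: node_attributes has ", nrow(attrs),
           " rows for ", n_total, " nodes")
    }
  }

  node_of <- split(seq_len(n_total), ind)
  graphs <- vector("list", n_graphs)
  for (k in seq_len(n_graphs)) {
    nodes <- node_of[[as.character(graph_ids[k])]]
    n <- length(nodes)
    local_id <- integer(n_total)
    local_id[nodes] <- seq_len(n)
    a <- matrix(0, n, n)
    if (nrow(edges)) {
      sel <- ind[edges$i] == graph_ids[k]
      if (any(sel)) {
        ii <- local_id[edges$i[sel]]
        jj <- local_id[edges$j[sel]]
        a[cbind(ii, jj)] <- 1
        a[cbind(jj, ii)] <- 1  # symmetrize regardless of dialect
      }
    }
    graphs[[k]] <- LabeledGraph(
      adjacency = a,
      nodeFeatures = if (is.null(attrs)) NULL else attrs[nodes, , drop = FALSE],
      nodeLabels = nl[nodes],
      nodeLabelMask = rep(has_node_labels, n),
      graphLabel = gl[k],
      graphId = sprintf("%s_%d", name, k)
    )
  }

  ds <- GraphDataset(graphs,
                     numGraphClasses = length(gl_levels),
                     numNodeClasses = length(nl_levels),
                     name = name)
  attr(ds, "labelMaps") <- list(graph = gl_levels, node = nl_levels)
  if (is.null(attrs)) {
    ds <- buildAdjacencyFeatures(ds)
  } else {
    attr(ds, "attrDim") <- ncol(attrs)
  }
  validObject(ds)
  ds
}

#' Write a dataset in TU Dortmund benchmark format
#'
#' Emits the TU file layout so that [readTuDataset()] recovers the dataset
#' exactly. Edges are written in both directions; labels are written 1-based
#' per the TU convention. Node features are written to
#' `<name>_node_attributes.txt` unless they are zero-padded adjacency rows
#' (which the reader reconstructs) or absent. The node-label file is written
#' only when every node label is observed.
#'
#' @param dataset a valid [GraphDataset-class]; must be non-empty.
#' @param directory output directory (created if needed).
#' @param name file prefix; defaults to the dataset name.
#' @return Invisibly, the character vector of files written.
#' @export
writeTuDataset <- function(dataset, directory, name = NULL) {
  stopifnot(is(dataset, "GraphDataset"))
  if (length(dataset@graphs) == 0L) {
    stop("refusing to write an empty dataset")
  }
  validObject(dataset)
  if (is.null(name)) name <- dataset@name
  if (!dir.exists(directory)) {
    ok <- dir.create(directory, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create directory '", directory, "'")
  }

  sizes <- vapply(dataset@graphs, numNodes, integer(1))
  offsets <- cumsum(c(0L, sizes[-length(sizes)]))

  ei <- integer(); ej <- integer()
  for (k in seq_along(dataset@graphs)) {
    a <- dataset@graphs[[k]]@adjacency
    idx <- which(a != 0, arr.ind = TRUE)  # both directions
    if (nrow(idx)) {
      ei <- c(ei, idx[, 1] + offsets[k])
      ej <- c(ej, idx[, 2] + offsets[k])
    }
  }
  files <- character()
  f_a <- tu_path(directory, name, "A")
  writeLines(paste(ei, ej, sep = ", "), f_a)
  files <- c(files, f_a)

  f_ind <- tu_path(directory, name, "graph_indicator")
  writeLines(as.character(rep(seq_along(sizes), sizes)), f_ind)
  files <- c(files, f_ind)

  f_gl <- tu_path(directory, name, "graph_labels")
  writeLines(as.character(vapply(dataset@graphs, graphLabel, integer(1)) + 1L), f_gl)
  files <- c(files, f_gl)

  masks <- unlist(lapply(dataset@graphs, function(g) g@nodeLabelMask))
  if (length(masks) && all(masks)) {
    f_nl <- tu_path(directory, name, "node_labels")
    nl <- unlist(lapply(dataset@graphs, nodeLabels))
    writeLines(as.character(nl + 1L), f_nl)
    files <- c(files, f_nl)
  }

  adj_feats <- isTRUE(attr(dataset, "adjacencyFeatures"))
  if (dataset@featureDim > 0L && !adj_feats) {
    f_na <- tu_path(directory, name, "node_attributes")
    feats <- do.call(rbind, lapply(dataset@graphs, nodeFeatures))
    writeLines(apply(feats, 1L, function(r) paste(format(r, digits = 17), collapse = ", ")),
               f_na)
    files <- c(files, f_na)
  }
  invisible(files)
}
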