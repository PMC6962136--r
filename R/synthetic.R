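# Synthetic labeled-graph collections with a controllable coupling between
# the node-label composition of a graph and its graph label, emulating the
# structure of molecular benchmarks (atoms = nodes with categorical types,
# bonds = edges, compound class = graph label). Used to exercise and
# benchmark the multi-task models without any external data.

#' Configuration for the synthetic graph generator
#'
#' @param numGraphs number of graphs.
#' @param nodesMin,nodesMax node-count range (inclusive, uniform).
#' @param numNodeClasses C_v (>= 2).
#' @param numGraphClasses C_G (>= 2).
#' @param edgeDensity Erdos-Renyi edge probability in (0, 1); graphs are
#'   resampled until connected.
#' @param rule coupling rule mapping a graph's node labels/topology to its
#'   graph label. `"majority-node-class"`: the label is the modal node class
#'   (node labels are drawn so the mode equals the drawn class).
#'   `"triangle-threshold"`: label 1 when the triangle count is at or above
#'   the count expected under the configuration's edge density, else 0.
#' @param labelNoise rho in `[0, 1)`: probability of replacing a graph label
#'   with a uniformly drawn different class after applying the rule.
#' @param attributeDim 0 = no continuous attributes (adjacency rows become
#'   features); > 0 = per-node attributes equal to the one-hot prototype of
#'   the node class (in the first `min(attributeDim, C_v)` coordinates) plus
#'   isotropic Gaussian noise with standard deviation `attributeNoise`.
#' @param attributeNoise noise SD of continuous attributes.
#' @param classBias probability mass the node-label distribution puts on the
#'   graph's own class; the remainder is split evenly over the other classes.
#' @param seed integer seed; all draws flow from it.
#' @return A list of class `"SynthConfig"`.
#' @export
synthConfig <- function(numGraphs = 100L, nodesMin = 10L, nodesMax = 20L,
                        numNodeClasses = 3L, numGraphClasses = 2L,
                        edgeDensity = 0.3, rule = "majority-node-class",
                        labelNoise = 0, attributeDim = NULL,
                        attributeNoise = 0.3, classBias = 0.6, seed = 1L) {
  if (is.null(attributeDim)) attributeDim <- as.integer(numNodeClasses)
  cfg <- list(numGraphs = as.integer(numGraphs),
              nodesMin = as.integer(nodesMin), nodesMax = as.integer(nodesMax),
              numNodeClasses = as.integer(numNodeClasses),
              numGraphClasses = as.integer(numGraphClasses),
              edgeDensity = edgeDensity, rule = match.arg(
                rule, c("majority-node-class", "triangle-threshold")),
              labelNoise = labelNoise, attributeDim = as.integer(attributeDim),
              attributeNoise = attributeNoise, classBias = classBias,
              seed = as.integer(seed))
  stopifnot(cfg$nodesMin >= 2L, cfg$nodesMax >= cfg$nodesMin,
            cfg$numNodeClasses >= 2L, cfg$numGraphClasses >= 2L,
            cfg$edgeDensity > 0, cfg$edgeDensity < 1,
            cfg$labelNoise >= 0, cfg$labelNoise < 1,
            cfg$classBias > 1 / cfg$numNodeClasses, cfg$classBias <= 1)
  class(cfg) <- "SynthConfig"
  cfg
}

count_triangles <- function(a) {
  sum(diag(a %*% a %*% a)) / 6
}

connected_er_graph <- function(n, p, max_tries = 200L) {
  for (k in seq_len(max_tries)) {
    a <- matrix(0, n, n)
    up <- which(upper.tri(a))
    a[up] <- as.numeric(stats::runif(length(up)) < p)
    a <- a + t(a)
    # connectivity via iterated reachability
    reach <- (diag(n) + a) %*% (diag(n) + a)
    for (i in seq_len(ceiling(log2(max(n, 2))))) reach <- reach %*% reach
    if (all(reach[1, ] > 0)) return(a)
  }
  stop("generation error: could not sample a connected graph with n = ", n,
       ", p = ", p, " after ", max_tries, " attempts")
}

#' Generate a synthetic labeled graph dataset
#'
#' Each graph is a connected Erdos-Renyi graph; node labels are drawn i.i.d.
#' from a distribution biased towards the graph's class, and the graph label
#' is the coupling rule applied to the realized labels/topology, flipped with
#' probability `labelNoise`. At `labelNoise = 0` the rule therefore holds
#' exactly on the emitted dataset, so a perfect classifier exists (Bayes
#' accuracy 1). Identical seeds give bit-identical datasets; the global RNG
#' state is left untouched.
#'
#' @param config a [synthConfig()] object.
#' @return A [GraphDataset-class] named `"synth"`.
#' @examples
#' d <- generateDataset(synthConfig(numGraphs = 5, seed = 7))
#' datasetStats(d)
#' @export
generateDataset <- function(config) {
  stopifnot(inherits(config, "SynthConfig"))
  withr::local_seed(config$seed)
  cg <- config$numGraphClasses
  cv <- config$numNodeClasses
  graphs <- vector("list", config$numGraphs)
  for (k in seq_len(config$numGraphs)) {
    n <- sample(config$nodesMin:config$nodesMax, 1L)
    a <- connected_er_graph(n, config$edgeDensity)
    y <- sample.int(cg, 1L) - 1L  # intended class
    probs <- rep((1 - config$classBias) / (cv - 1), cv)
    probs[(y %% cv) + 1L] <- config$classBias
    if (config$rule == "majority-node-class") {
      for (try in seq_len(500L)) {
        labs <- sample.int(cv, n, replace = TRUE, prob = probs) - 1L
        tab <- tabulate(labs + 1L, cv)
        modal <- which.max(tab) - 1L
        if (modal == (y %% cv) && sum(tab == max(tab)) == 1L) break
        if (try == 500L) stop("generation error: modal-class resampling failed")
      }
      label <- modal %% cg
    } else {  # triangle-threshold
      labs <- sample.int(cv, n, replace = TRUE, prob = probs) - 1L
      thr <- choose(n, 3) * config$edgeDensity^3  # expected triangle count
      label <- as.integer(count_triangles(a) >= thr)
    }
    if (config$labelNoise > 0 && stats::runif(1) < config$labelNoise) {
      label <- (label + sample.int(cg - 1L, 1L)) %% cg
    }
    feats <- NULL
    if (config$attributeDim > 0L) {
      feats <- matrix(stats::rnorm(n * config$attributeDim,
                                   sd = config$attributeNoise),
                      n, config$attributeDim)
      proto_col <- (labs %% config$attributeDim) + 1L
      feats[cbind(seq_len(n), proto_col)] <-
        feats[cbind(seq_len(n), proto_col)] + 1
    }
    graphs[[k]] <- LabeledGraph(adjacency = a, nodeFeatures = feats,
                                nodeLabels = labs, graphLabel = label,
                                graphId = sprintf("synth_%d", k))
  }
  ds <- GraphDataset(graphs, numGraphClasses = cg, numNodeClasses = cv,
                     name = "synth")
  if (config$attributeDim > 0L) {
    attr(ds, "attrDim") <- config$attributeDim
  } else {
    ds <- buildAdjacencyFeatures(ds)
  }
  ds
}

#' Write a suite of small TU-format fixture datasets
#'
#' Emits four miniature datasets covering the structural corner cases the
#' loaders must handle: continuous attributes, label-only graphs, a dataset
#' containing an edgeless graph, and a dataset containing single-node graphs.
#' Regenerating with the same seed reproduces the files byte for byte.
#'
#' @param directory output directory (one subdirectory per fixture).
#' @param seed integer seed.
#' @return Invisibly, a named list of the dataset directories written.
#' @export
generateFixtureSuite <- function(directory, seed = 42L) {
  if (!dir.exists(directory)) dir.create(directory, recursive = TRUE)
  out <- list()

  write_one <- function(ds, label) {
    sub <- file.path(directory, label)
    dir.create(sub, showWarnings = FALSE)
    writeTuDataset(ds, sub, name = label)
    out[[label]] <<- sub
  }

  attributed <- generateDataset(synthConfig(numGraphs = 6L, nodesMin = 4L,
                                            nodesMax = 8L, attributeDim = 2L,
                                            seed = seed))
  attributed@name <- "attributed"
  write_one(attributed, "attributed")

  labelonly <- generateDataset(synthConfig(numGraphs = 6L, nodesMin = 4L,
                                           nodesMax = 8L, attributeDim = 0L,
                                           seed = seed + 1L))
  labelonly@name <- "labelonly"
  write_one(labelonly, "labelonly")

  # a 3-graph set whose middle graph has no edges
  tri <- matrix(c(0, 1, 1, 1, 0, 1, 1, 1, 0), 3)
  edgeless <- GraphDataset(list(
    LabeledGraph(tri, nodeLabels = c(0L, 0L, 1L), graphLabel = 0L, graphId = "edgeless_1"),
    LabeledGraph(matrix(0, 3, 3), nodeLabels = c(1L, 1L, 0L), graphLabel = 1L, graphId = "edgeless_2"),
    LabeledGraph(tri, nodeLabels = c(1L, 0L, 1L), graphLabel = 1L, graphId = "edgeless_3")),
    name = "edgeless")
  write_one(buildAdjacencyFeatures(edgeless), "edgeless")

  # single-node graphs mixed with a path
  path2 <- matrix(c(0, 1, 1, 0), 2)
  singlenode <- GraphDataset(list(
    LabeledGraph(matrix(0, 1, 1), nodeLabels = 0L, graphLabel = 0L, graphId = "singlenode_1"),
    LabeledGraph(path2, nodeLabels = c(0L, 1L), graphLabel = 1L, graphId = "singlenode_2"),
    LabeledGraph(matrix(0, 1, 1), nodeLabels = 1L, graphLabel = 0L, graphId = "singlenode_3")),
    name = "singlenode")
  write_one(buildAdjacencyFeatures(singlenode), "singlenode")

  invisible(out)
}
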