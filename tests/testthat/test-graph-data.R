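test_that("hand-authored TU fixture of two triangles parses correctly", {
  dir <- withr::local_tempdir()
  writeLines(c("1, 2", "2, 1", "1, 3", "3, 1", "2, 3", "3, 2",
               "4, 5", "5, 4", "4, 6", "6, 4", "5, 6", "6, 5"),
             file.path(dir, "tri_A.txt"))
  writeLines(as.character(c(1, 1, 1, 2, 2, 2)),
             file.path(dir, "tri_graph_indicator.txt"))
  writeLines(c("1", "2"), file.path(dir, "tri_graph_labels.txt"))
  writeLines(as.character(c(1, 1, 2, 2, 1, 1)),
             file.path(dir, "tri_node_labels.txt"))

  ds <- readTuDataset(dir, "tri")
  expect_equal(numGraphs(ds), 2L)
  expect_equal(numGraphClasses(ds), 2L)
  expect_equal(numNodeClasses(ds), 2L)
  for (k in 1:2) {
    expect_equal(numNodes(ds[[k]]), 3L)
    expect_equal(sum(adjacency(ds[[k]])) / 2, 3)  # 3 undirected edges
  }
  # labels re-indexed to 0-based
  expect_equal(graphLabel(ds[[1]]), 0L)
  expect_equal(graphLabel(ds[[2]]), 1L)
  expect_equal(nodeLabels(ds[[1]]), c(0L, 0L, 1L))
  # adjacency-as-features fallback, padded to the max node count
  expect_equal(featureDim(ds), 3L)
  expect_equal(nodeFeatures(ds[[1]]), adjacency(ds[[1]]))
})

test_that("reader symmetrizes single-direction edge lists and drops self-loops", {
  dir <- withr::local_tempdir()
  # each edge listed once + one self-loop
  writeLines(c("1, 2", "2, 3", "2, 2"), file.path(dir, "one_A.txt"))
  writeLines(as.character(c(1, 1, 1)), file.path(dir, "one_graph_indicator.txt"))
  writeLines("1", file.path(dir, "one_graph_labels.txt"))
  expect_warning(ds <- readTuDataset(dir, "one"), "self-loop")
  expect_equal(adjacency(ds[[1]]), path3_adj)
})

test_that("reader rejects missing or inconsistent files", {
  dir <- withr::local_tempdir()
  writeLines("1, 2", file.path(dir, "bad_A.txt"))
  expect_error(readTuDataset(dir, "bad"), "missing mandatory file")
  writeLines(as.character(c(1, 1)), file.path(dir, "bad_graph_indicator.txt"))
  writeLines("1", file.path(dir, "bad_graph_labels.txt"))
  # node index out of range
  writeLines("1, 7", file.path(dir, "bad_A.txt"))
  expect_error(readTuDataset(dir, "bad"), "integrity")
  # cross-graph edge
  writeLines(as.character(c(1, 2)), file.path(dir, "bad_graph_indicator.txt"))
  writeLines(c("1", "1"), file.path(dir, "bad_graph_labels.txt"))
  writeLines("1, 2", file.path(dir, "bad_A.txt"))
  expect_error(readTuDataset(dir, "bad"), "different graphs")
})

test_that("write/read round trip is the identity on valid datasets", {
  for (attr_dim in c(0L, 2L)) {
    d <- generateDataset(synthConfig(numGraphs = 10L, nodesMin = 3L,
                                     nodesMax = 7L, attributeDim = attr_dim,
                                     seed = 5L))
    dir <- withr::local_tempdir()
    files <- writeTuDataset(d, dir)
    d2 <- readTuDataset(dir, "synth")
    expect_equal(numGraphs(d2), numGraphs(d))
    expect_equal(featureDim(d2), featureDim(d))
    expect_equal(numNodeClasses(d2), numNodeClasses(d))
    for (k in seq_len(numGraphs(d))) {
      expect_identical(adjacency(d2[[k]]), adjacency(d[[k]]))
      expect_equal(nodeFeatures(d2[[k]]), nodeFeatures(d[[k]]))
      expect_identical(nodeLabels(d2[[k]]), nodeLabels(d[[k]]))
      expect_identical(graphLabel(d2[[k]]), graphLabel(d[[k]]))
    }
    # label-only datasets emit exactly 4 files (no attribute file)
    if (attr_dim == 0L) expect_length(files, 4L)
  }
})

test_that("writer refuses degenerate input", {
  d <- generateDataset(synthConfig(numGraphs = 2L, seed = 1L))
  d@graphs <- list()
  expect_error(writeTuDataset(d, withr::local_tempdir()), "empty")
})

test_that("adjacency features pad with zeros to the requested width", {
  g <- LabeledGraph(matrix(c(0, 1, 1, 0), 2))
  d <- buildAdjacencyFeatures(GraphDataset(list(g)), padTo = 4L)
  expect_equal(nodeFeatures(d[[1]]),
               rbind(c(0, 1, 0, 0), c(1, 0, 0, 0)))
  # edgeless graph: all-zero features
  e <- buildAdjacencyFeatures(GraphDataset(list(LabeledGraph(matrix(0, 3, 3)))))
  expect_true(all(nodeFeatures(e[[1]]) == 0))
  # no padding needed: features equal the adjacency itself
  tr <- buildAdjacencyFeatures(GraphDataset(list(make_graph(triangle_adj))),
                               padTo = 3L)
  expect_equal(nodeFeatures(tr[[1]]), triangle_adj)
  # too-small pad is a dimension error
  expect_error(buildAdjacencyFeatures(GraphDataset(list(make_graph(triangle_adj))),
                                      padTo = 2L), "dimension")
})

test_that("batching is block-diagonal and unbatching inverts it", {
  g1 <- make_graph(triangle_adj, d = 2L, labels = c(0L, 1L, 0L), id = "a")
  g2 <- make_graph(triangle_adj, d = 2L, labels = c(1L, 1L, 0L), glabel = 1L, id = "b")
  b <- batchGraphs(list(g1, g2))
  expect_equal(Matrix::nnzero(b@blockAdjacency), 12L)  # 2 x 3 edges x 2 dirs
  expect_equal(b@graphMembership, rep(1:2, each = 3L))
  expect_true(all(as.matrix(b@blockAdjacency)[1:3, 4:6] == 0))
  back <- unbatchGraphs(b)
  for (k in 1:2) {
    orig <- list(g1, g2)[[k]]
    expect_identical(adjacency(back[[k]]), adjacency(orig))
    expect_identical(nodeLabels(back[[k]]), nodeLabels(orig))
    expect_identical(back[[k]]@graphId, orig@graphId)
  }
  # singleton batch
  b1 <- batchGraphs(list(g1))
  expect_equal(b1@graphMembership, rep(1L, 3L))
  expect_error(batchGraphs(list()), "empty")
})

test_that("round trip through batching preserves random datasets", {
  set.seed(11)
  gs <- lapply(1:5, function(k) rand_graph(sample(2:9, 1), id = paste0("g", k)))
  back <- unbatchGraphs(batchGraphs(gs))
  for (k in seq_along(gs)) {
    expect_identical(adjacency(back[[k]]), adjacency(gs[[k]]))
    expect_equal(nodeFeatures(back[[k]]), nodeFeatures(gs[[k]]))
  }
})

test_that("dataset statistics count nodes and undirected edges correctly", {
  d1 <- GraphDataset(list(make_graph(triangle_adj)))
  s1 <- datasetStats(d1)
  expect_equal(s1$avgNodes, 3)
  expect_equal(s1$avgEdges, 3)
  d2 <- GraphDataset(list(make_graph(matrix(0, 2, 2)),
                          make_graph(rand_adj(4), id = "h")))
  expect_equal(datasetStats(d2)$avgNodes, 3)
})

test_that("LabeledGraph validity rejects malformed adjacency", {
  expect_error(LabeledGraph(matrix(c(0, 1, 0, 0), 2)), "symmetric")
  expect_error(LabeledGraph(matrix(c(1, 1, 1, 0), 2)), "diagonal")
  expect_error(LabeledGraph(matrix(c(0, 2, 2, 0), 2)), "0/1")
})
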