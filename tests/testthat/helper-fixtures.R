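# Shared fixtures: tiny hand-built graphs, seeded random graphs, and
# independent dense brute-force oracles (explicit per-node loops) for the
# layer equations and losses.

triangle_adj <- matrix(c(0, 1, 1, 1, 0, 1, 1, 1, 0), 3)
path3_adj <- matrix(c(0, 1, 0, 1, 0, 1, 0, 1, 0), 3)

make_graph <- function(adj, d = 1L, labels = NULL, glabel = 0L, id = "g") {
  n <- nrow(adj)
  LabeledGraph(adj, nodeFeatures = matrix(1, n, d),
               nodeLabels = if (is.null(labels)) rep(0L, n) else labels,
               graphLabel = glabel, graphId = id)
}

rand_adj <- function(n, p = 0.5) {
  a <- matrix(0, n, n)
  up <- which(upper.tri(a))
  a[up] <- as.numeric(runif(length(up)) < p)
  a + t(a)
}

rand_graph <- function(n, d = 3L, p = 0.5, cv = 3L, cg = 2L, id = "r") {
  LabeledGraph(rand_adj(n, p), nodeFeatures = matrix(rnorm(n * d), n, d),
               nodeLabels = sample.int(cv, n, replace = TRUE) - 1L,
               graphLabel = sample.int(cg, 1L) - 1L, graphId = id)
}

rand_batch <- function(n_graphs = 3L, nmax = 8L, d = 3L) {
  batchGraphs(lapply(seq_len(n_graphs), function(k) {
    rand_graph(sample(2:nmax, 1L), d = d, id = paste0("r", k))
  }))
}

# ---- dense brute-force oracles ---------------------------------------------

oracle_gin_aggregate <- function(adj, h, eps) {
  out <- matrix(0, nrow(h), ncol(h))
  for (v in seq_len(nrow(h))) {
    acc <- (1 + eps) * h[v, ]
    for (u in seq_len(nrow(h))) {
      if (adj[v, u] != 0) acc <- acc + h[u, ]
    }
    out[v, ] <- acc
  }
  out
}

oracle_sage <- function(adj, h, W, b, normalize = TRUE, activation = "relu") {
  n <- nrow(h)
  out <- NULL
  for (v in seq_len(n)) {
    nb <- which(adj[v, ] != 0)
    m <- if (length(nb)) colSums(h[nb, , drop = FALSE] * adj[v, nb]) / sum(adj[v, nb])
         else numeric(ncol(h))
    z <- as.vector(c(h[v, ], m) %*% W) + as.vector(b)
    if (activation == "relu") z <- pmax(z, 0)
    if (normalize) {
      r <- sqrt(sum(z^2))
      if (r > 1e-12) z <- z / r
    }
    out <- rbind(out, z)
  }
  unname(out)
}

oracle_row_softmax <- function(x) {
  out <- matrix(0, nrow(x), ncol(x))
  for (i in seq_len(nrow(x))) {
    e <- exp(x[i, ] - max(x[i, ]))
    out[i, ] <- e / sum(e)
  }
  out
}

oracle_xent <- function(scores, labels, mask = NULL, reduction = "mean") {
  if (is.null(mask)) mask <- rep(TRUE, nrow(scores))
  p <- oracle_row_softmax(scores)
  tot <- 0
  for (i in which(mask)) tot <- tot - log(p[i, labels[i] + 1L])
  if (reduction == "mean") tot / sum(mask) else tot
}

rel_err <- function(a, b) {
  max(abs(a - b)) / max(1e-12, max(abs(a)), max(abs(b)))
}

# ---- finite-difference gradients (with batch-norm state restored) ----------

bn_snapshot <- function(model) as.list(model$bn$stats)
bn_restore <- function(model, snap) model$bn$stats <- snap

fd_gradient <- function(batch, model, name, index, alpha = 1, h = 1e-5,
                        training = TRUE) {
  snap <- bn_snapshot(model)
  val_at <- function(delta) {
    m <- model
    m$par[[name]][index] <- m$par[[name]][index] + delta
    l <- lossAndGradients(batch, m, alpha = alpha, training = training)$loss
    bn_restore(model, snap)
    l
  }
  (val_at(h) - val_at(-h)) / (2 * h)
}
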