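# Minimal reverse-mode automatic differentiation on dense matrices.
#
# A tape is an environment accumulating nodes in topological order; each node
# holds its value (a base matrix), the ids of its parents, and a backward
# closure mapping the upstream gradient to per-parent gradients. Backward
# sweeps the tape once in reverse id order. All model training in the package
# runs through these primitives; inference uses plain matrix code and the two
# are cross-checked in the test suite.

ad_tape <- function() {
  tape <- new.env(parent = emptyenv())
  tape$nodes <- vector("list", 64L)
  tape$n <- 0L
  tape
}

# value: base matrix; parents: list of ad handles; back: function(grad) ->
# list of gradients aligned with parents (NULL entries allowed).
ad_node <- function(tape, value, parents = list(), back = NULL,
                    needs = NULL) {
  if (is.null(needs)) {
    needs <- FALSE
    for (p in parents) if (tape$nodes[[p$id]]$needs) { needs <- TRUE; break }
  }
  i <- tape$n + 1L
  if (i > length(tape$nodes)) {
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  }
  tape$nodes[[i]] <- list(
    value = value,
    parents = vapply(parents, function(p) p$id, integer(1)),
    back = back,
    needs = needs
  )
  tape$n <- i
  structure(list(tape = tape, id = i), class = "ad")
}

ad_value <- function(x) x$tape$nodes[[x$id]]$value

ad_leaf <- function(tape, value, needs = FALSE) {
  if (!is.matrix(value)) value <- as.matrix(value)
  ad_node(tape, value, needs = needs)
}

# Backward pass from a scalar root; returns list indexed by node id with
# accumulated gradients (NULL where not needed / not reached).
ad_backward <- function(root) {
  tape <- root$tape
  grads <- vector("list", tape$n)
  grads[[root$id]] <- matrix(1, 1, 1)
  for (i in seq(root$id, 1L)) {
    g <- grads[[i]]
    if (is.null(g)) next
    node <- tape$nodes[[i]]
    if (is.null(node$back) || !node$needs) next
    pg <- node$back(g)
    for (k in seq_along(node$parents)) {
      j <- node$parents[k]
      if (is.null(pg[[k]]) || !tape$nodes[[j]]$needs) next
      grads[[j]] <- if (is.null(grads[[j]])) pg[[k]] else grads[[j]] + pg[[k]]
    }
  }
  grads
}

# ---- primitives -------------------------------------------------------------

ad_matmul <- function(a, b) {
  av <- ad_value(a); bv <- ad_value(b)
  ad_node(a$tape, av %*% bv, list(a, b), back = function(g) {
    list(g %*% t(bv), crossprod(av, g))
  })
}

# Multiply by a fixed (untracked) matrix on the left; m may be sparse.
ad_lmul_const <- function(m, h) {
  ad_node(h$tape, as.matrix(m %*% ad_value(h)), list(h), back = function(g) {
    list(as.matrix(Matrix::crossprod(m, g)))
  })
}

ad_t <- function(a) {
  ad_node(a$tape, t(ad_value(a)), list(a), back = function(g) list(t(g)))
}

ad_add <- function(a, b) {
  ad_node(a$tape, ad_value(a) + ad_value(b), list(a, b),
          back = function(g) list(g, g))
}

# a: n x w, bias: 1 x w
ad_addbias <- function(a, bias) {
  bv <- ad_value(bias)
  ad_node(a$tape, col_plus(ad_value(a), as.vector(bv)), list(a, bias),
          back = function(g) list(g, matrix(colSums(g), 1L)))
}

ad_scale <- function(a, s) {
  ad_node(a$tape, ad_value(a) * s, list(a), back = function(g) list(g * s))
}

ad_mul <- function(a, b) {
  av <- ad_value(a); bv <- ad_value(b)
  ad_node(a$tape, av * bv, list(a, b),
          back = function(g) list(g * bv, g * av))
}

# Divide each column of num (n x w) by den (n x 1); gradient flows into both.
ad_coldiv <- function(num, den, eps = 1e-12) {
  nv <- ad_value(num); dv <- pmax(as.vector(ad_value(den)), eps)
  ad_node(num$tape, nv / dv, list(num, den), back = function(g) {
    list(g / dv, matrix(-rowSums(g * nv / dv^2), ncol = 1L))
  })
}

ad_relu <- function(a) {
  v <- ad_value(a)
  ad_node(a$tape, v * (v > 0), list(a),
          back = function(g) list(g * (v > 0)))
}

ad_cbind <- function(xs) {
  vals <- lapply(xs, ad_value)
  widths <- vapply(vals, ncol, integer(1))
  ends <- cumsum(widths)
  starts <- ends - widths + 1L
  ad_node(xs[[1]]$tape, do.call(cbind, vals), xs, back = function(g) {
    lapply(seq_along(xs), function(k) g[, starts[k]:ends[k], drop = FALSE])
  })
}

ad_rbind <- function(xs) {
  vals <- lapply(xs, ad_value)
  heights <- vapply(vals, nrow, integer(1))
  ends <- cumsum(heights)
  starts <- ends - heights + 1L
  ad_node(xs[[1]]$tape, do.call(rbind, vals), xs, back = function(g) {
    lapply(seq_along(xs), function(k) g[starts[k]:ends[k], , drop = FALSE])
  })
}

ad_rowslice <- function(a, idx) {
  v <- ad_value(a)
  nr <- nrow(v); nc <- ncol(v)
  ad_node(a$tape, v[idx, , drop = FALSE], list(a), back = function(g) {
    out <- matrix(0, nr, nc)
    out[idx, ] <- g
    list(out)
  })
}

ad_colslice <- function(a, idx) {
  v <- ad_value(a)
  nr <- nrow(v); nc <- ncol(v)
  ad_node(a$tape, v[, idx, drop = FALSE], list(a), back = function(g) {
    out <- matrix(0, nr, nc)
    out[, idx] <- g
    list(out)
  })
}

ad_rowsoftmax <- function(a) {
  v <- ad_value(a)
  s <- row_softmax(v)
  ad_node(a$tape, s, list(a), back = function(g) {
    list(s * (g - rowSums(g * s)))
  })
}

# Row-wise l2 normalization; zero rows map to zero rows.
ad_l2norm_rows <- function(a, eps = 1e-12) {
  v <- ad_value(a)
  r <- pmax(sqrt(rowSums(v^2)), eps)
  ad_node(a$tape, v / r, list(a), back = function(g) {
    list(g / r - v * (rowSums(g * v) / r^3))
  })
}

# Column-wise batch normalization. `state` is an environment keyed by `key`
# holding running first/second central moments; training mode uses batch
# statistics and updates the running ones as a side effect.
ad_batchnorm <- function(a, gamma, beta, state, key, training,
                         momentum = 0.1, eps = 1e-5) {
  v <- ad_value(a)
  m <- nrow(v)
  if (is.null(state$stats[[key]])) {
    state$stats[[key]] <- list(mean = numeric(ncol(v)) * 0,
                               var = rep(1, ncol(v)))
  }
  if (training) {
    mu <- colMeans(v)
    xc <- col_plus(v, -mu)
    va <- colMeans(xc^2)
    state$stats[[key]]$mean <- (1 - momentum) * state$stats[[key]]$mean + momentum * mu
    state$stats[[key]]$var <- (1 - momentum) * state$stats[[key]]$var + momentum * va
  } else {
    mu <- state$stats[[key]]$mean
    va <- state$stats[[key]]$var
    xc <- col_plus(v, -mu)
  }
  sd_ <- sqrt(va + eps)
  xhat <- col_times(xc, 1 / sd_)
  gv <- as.vector(ad_value(gamma)); bv <- as.vector(ad_value(beta))
  out <- col_affine(xhat, gv, bv)
  ad_node(a$tape, out, list(a, gamma, beta), back = function(g) {
    dgamma <- matrix(colSums(g * xhat), 1L)
    dbeta <- matrix(colSums(g), 1L)
    if (training) {
      gs <- col_times(g, gv)
      s1 <- colSums(gs)
      s2 <- colSums(gs * xhat)
      dx <- col_times(col_plus(gs, -s1 / m) - col_times(xhat, s2 / m), 1 / sd_)
    } else {
      dx <- col_times(g, gv / sd_)
    }
    list(dx, dgamma, dbeta)
  })
}

# Sum rows of a by group (groups in 1..B); result row b is the sum over
# nodes with groups == b.
ad_groupsum <- function(a, groups, B) {
  v <- ad_value(a)
  out <- group_rowsum(v, groups, B)
  ad_node(a$tape, out, list(a), back = function(g) {
    list(g[groups, , drop = FALSE])
  })
}

# Masked softmax cross-entropy with integer labels in 1..C.
# reduction "mean" divides by the number of unmasked rows.
ad_xent <- function(logits, labels, mask, reduction = "mean") {
  v <- ad_value(logits)
  p <- row_softmax(v)
  keep <- as.logical(mask)
  cnt <- sum(keep)
  denom <- if (reduction == "mean") max(cnt, 1L) else 1
  if (cnt == 0L) {
    val <- 0
  } else {
    idx <- cbind(which(keep), labels[keep])
    val <- -sum(log(pmax(p[idx], 1e-300))) / denom
  }
  ad_node(logits$tape, matrix(val, 1L, 1L), list(logits), back = function(g) {
    gm <- p
    ik <- which(keep)
    if (length(ik)) {
      gm[cbind(ik, labels[ik])] <- gm[cbind(ik, labels[ik])] - 1
    }
    gm[!keep, ] <- 0
    list(gm * (as.numeric(g) / denom))
  })
}

# Assemble square blocks into one block-diagonal matrix node.
ad_blockdiag <- function(xs) {
  vals <- lapply(xs, ad_value)
  sizes <- vapply(vals, nrow, integer(1))
  ends <- cumsum(sizes)
  starts <- ends - sizes + 1L
  total <- sum(sizes)
  out <- matrix(0, total, total)
  for (k in seq_along(vals)) {
    out[starts[k]:ends[k], starts[k]:ends[k]] <- vals[[k]]
  }
  ad_node(xs[[1]]$tape, out, xs, back = function(g) {
    lapply(seq_along(xs), function(k) {
      g[starts[k]:ends[k], starts[k]:ends[k], drop = FALSE]
    })
  })
}

# ---- shared numeric helpers (also used by the plain inference path) ---------

row_softmax <- function(x) {
  m <- x[cbind(seq_len(nrow(x)), max.col(x, ties.method = "first"))]
  e <- exp(x - m)
  e / rowSums(e)
}

# fast column-wise arithmetic (recycling down columns; avoids sweep/aperm)
col_plus <- function(x, v) x + rep(v, each = nrow(x))
col_times <- function(x, v) x * rep(v, each = nrow(x))
col_affine <- function(x, scale, shift) {
  n <- nrow(x)
  x * rep(scale, each = n) + rep(shift, each = n)
}

group_rowsum <- function(x, groups, B) {
  out <- rowsum(x, group = factor(groups, levels = seq_len(B)))
  rownames(out) <- NULL
  out
}
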