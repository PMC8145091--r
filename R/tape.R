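# Minimal reverse-mode automatic differentiation on dense matrices.
#
# Every value on the tape is a plain R matrix.  A node is an environment
# holding the value (`v`), its parent nodes (`par`), a backward closure
# (`bfn`, mapping the node's accumulated gradient to a list of parent
# gradients) and the accumulated gradient itself (`g`).  Nodes are created
# in topological order, so tape_backward() simply walks ids in reverse.
# The engine supports exactly the operations the hierarchical encoder and
# the diagnosis head need; it is not a general tensor library.

tape_new <- function() {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- vector("list", 512L)
  tp$n <- 0L
  tp
}

tp_node <- function(tape, value, parents = NULL, backward = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$v <- value
  nd$par <- parents
  nd$bfn <- backward
  nd$g <- NULL
  n <- tape$n + 1L
  if (n > length(tape$nodes)) {
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  }
  nd$id <- n
  tape$nodes[[n]] <- nd
  tape$n <- n
  nd
}

tp_const <- function(tape, m) {
  if (!is.matrix(m)) m <- as.matrix(m)
  tp_node(tape, m)
}

# Parameter leaf: identical to a constant, but callers keep a handle so the
# accumulated gradient can be read back after tape_backward().
tp_param <- function(tape, m) tp_const(tape, m)

tape_backward <- function(tape, out) {
  stopifnot(length(out$v) == 1L)
  out$g <- matrix(1, 1L, 1L)
  for (i in seq(out$id, 1L)) {
    nd <- tape$nodes[[i]]
    if (is.null(nd) || is.null(nd$g) || is.null(nd$bfn)) next
    pg <- nd$bfn(nd$g)
    for (j in seq_along(nd$par)) {
      gj <- pg[[j]]
      if (is.null(gj)) next
      p <- nd$par[[j]]
      p$g <- if (is.null(p$g)) gj else p$g + gj
    }
  }
  invisible(out)
}

## ---- primitive operations ----

tp_mm <- function(tape, a, b) {
  tp_node(tape, a$v %*% b$v, list(a, b), function(g) {
    list(g %*% t(b$v), t(a$v) %*% g)
  })
}

tp_t <- function(tape, a) {
  tp_node(tape, t(a$v), list(a), function(g) list(t(g)))
}

tp_add <- function(tape, a, b) {
  tp_node(tape, a$v + b$v, list(a, b), function(g) list(g, g))
}

# Add a 1 x k bias row to every row of an n x k matrix.
tp_addvec <- function(tape, a, b) {
  v <- a$v + rep(b$v, each = nrow(a$v))
  tp_node(tape, v, list(a, b), function(g) {
    list(g, matrix(colSums(g), 1L))
  })
}

tp_mul <- function(tape, a, b) {
  tp_node(tape, a$v * b$v, list(a, b), function(g) list(g * b$v, g * a$v))
}

# Multiply each column of X by a constant length-n vector (no gradient to m).
tp_colmulc <- function(tape, x, m) {
  tp_node(tape, x$v * m, list(x), function(g) list(g * m))
}

# Multiply each column of X by a column-vector node a (n x 1).
tp_colmul <- function(tape, x, a) {
  av <- a$v[, 1L]
  tp_node(tape, x$v * av, list(x, a), function(g) {
    list(g * av, matrix(rowSums(g * x$v), ncol = 1L))
  })
}

# Elementwise multiply by a constant 0/1 (or real) mask matrix.
tp_mulc <- function(tape, x, m) {
  tp_node(tape, x$v * m, list(x), function(g) list(g * m))
}

tp_onem <- function(tape, a) {                        # 1 - a
  tp_node(tape, 1 - a$v, list(a), function(g) list(-g))
}

tp_tanh <- function(tape, a) {
  v <- tanh(a$v)
  tp_node(tape, v, list(a), function(g) list(g * (1 - v * v)))
}

tp_sigmoid <- function(tape, a) {
  v <- 1 / (1 + exp(-a$v))
  tp_node(tape, v, list(a), function(g) list(g * v * (1 - v)))
}

tp_cbind <- function(tape, ...) {
  parents <- list(...)
  widths <- vapply(parents, function(p) ncol(p$v), 0L)
  v <- do.call(cbind, lapply(parents, function(p) p$v))
  ends <- cumsum(widths)
  starts <- c(1L, head(ends, -1L) + 1L)
  tp_node(tape, v, parents, function(g) {
    lapply(seq_along(parents), function(j) g[, starts[j]:ends[j], drop = FALSE])
  })
}

# Gather rows (duplicates allowed -- used for embedding lookup); backward
# scatter-adds gradients into the source rows.
tp_rows <- function(tape, a, idx) {
  nr <- nrow(a$v)
  tp_node(tape, a$v[idx, , drop = FALSE], list(a), function(g) {
    rs <- rowsum(g, group = idx)
    ga <- matrix(0, nr, ncol(g))
    ga[as.integer(rownames(rs)), ] <- rs
    list(ga)
  })
}

tp_col <- function(tape, a, j) {
  tp_node(tape, a$v[, j, drop = FALSE], list(a), function(g) {
    ga <- matrix(0, nrow(a$v), ncol(a$v))
    ga[, j] <- g
    list(ga)
  })
}

# Row-wise softmax restricted to positions where the constant 0/1 mask is 1;
# masked positions get exactly zero.  Rows with no unmasked position yield
# an all-zero row (legal: a record may have no surviving knowledge).
tp_masked_softmax <- function(tape, s, mask) {
  z <- s$v
  z[mask == 0] <- -Inf
  mx <- apply(z, 1L, max)
  mx[!is.finite(mx)] <- 0
  e <- exp(z - mx)
  e[mask == 0] <- 0
  rs <- rowSums(e)
  a <- e / ifelse(rs > 0, rs, 1)
  tp_node(tape, a, list(s), function(g) {
    list((g - rowSums(g * a)) * a)
  })
}

# Renormalise each row to sum to one (all-zero rows stay zero).  Used after
# top-k masking of attention weights.
tp_renorm_rows <- function(tape, x) {
  s <- rowSums(x$v)
  pos <- s > 0
  y <- x$v / ifelse(pos, s, 1)
  y[!pos, ] <- 0
  tp_node(tape, y, list(x), function(g) {
    gx <- (g - rowSums(g * y)) / ifelse(pos, s, 1)
    gx[!pos, ] <- 0
    list(gx)
  })
}

# Numerically stable mean-over-rows, sum-over-columns binary cross-entropy
# with logits; gradient is (sigmoid(z) - y) / n.
tp_bce_logits <- function(tape, logits, y) {
  z <- logits$v
  n <- nrow(z)
  ll <- pmax(z, 0) - z * y + log1p(exp(-abs(z)))
  v <- matrix(sum(ll) / n, 1L, 1L)
  tp_node(tape, v, list(logits), function(g) {
    list(g[1L] * (1 / (1 + exp(-z)) - y) / n)
  })
}
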