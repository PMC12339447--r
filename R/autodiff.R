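# Minimal reverse-mode automatic differentiation on numeric matrices.
#
# A "node" is an environment holding a value, an (initially NULL) gradient,
# its parent nodes, and one vector-Jacobian-product closure per parent.
# Nodes are appended to the active tape in creation order; backward() walks
# the tape in reverse, accumulating gradients. Ops accept either nodes or
# plain matrices; plain inputs are treated as constants (no gradient), and
# when no argument is a node the op computes the plain value, so the same
# layer code serves both training and inference.

.rt <- new.env(parent = emptyenv())
.rt$tape <- NULL

# The tape is an intrusive linked list: each node keeps a `prev` pointer to
# the node created before it, so appending is O(1) (a list held in an
# environment would be copied on every append).
new_tape <- function() {
  tp <- new.env(parent = emptyenv())
  tp$last <- NULL
  tp
}

#' Run an expression with a fresh autodiff tape
#'
#' @param expr expression building a computation graph.
#' @return the value of `expr`; gradients become available after
#'   [ad_backward()].
#' @keywords internal
with_tape <- function(expr) {
  old <- .rt$tape
  .rt$tape <- new_tape()
  on.exit(.rt$tape <- old)
  expr
}

is_node <- function(x) is.environment(x)
nval <- function(x) if (is.environment(x)) x$value else x

record <- function(value, parents, vjps) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  nd$parents <- parents
  nd$vjps <- vjps
  tp <- .rt$tape
  if (is.null(tp)) rt_error("no active tape; wrap training in with_tape()",
                            "rt_internal_error")
  nd$prev <- tp$last
  tp$last <- nd
  nd
}

# Wrap a parameter matrix as a differentiable leaf on the active tape.
ad_leaf <- function(value) record(value, list(), list())

# Accumulate gradients from a scalar (1x1) loss node back to every leaf,
# walking the tape chain in reverse creation order.
ad_backward <- function(loss) {
  tp <- .rt$tape
  loss$grad <- matrix(1, 1, 1)
  nd <- tp$last
  while (!is.null(nd)) {
    if (!is.null(nd$grad) && length(nd$parents)) {
      for (j in seq_along(nd$parents)) {
        p <- nd$parents[[j]]
        g <- nd$vjps[[j]](nd$grad)
        p$grad <- if (is.null(p$grad)) g else p$grad + g
      }
    }
    nd <- nd$prev
  }
  invisible(NULL)
}

# --- ops ---------------------------------------------------------------------

# Build a node when any input is a node; otherwise compute plainly.
emit <- function(value, ins, vjps) {
  live <- vapply(ins, is_node, logical(1))
  if (!any(live)) return(value)
  record(value, ins[live], vjps[live])
}

op_mm <- function(a, b) {
  va <- nval(a); vb <- nval(b)
  emit(va %*% vb, list(a, b), list(
    function(g) g %*% t(vb),
    function(g) t(va) %*% g
  ))
}

# b may be a matrix of equal shape, a 1 x ncol(a) row vector (broadcast over
# rows), or a plain scalar.
op_add <- function(a, b) {
  va <- nval(a); vb <- nval(b)
  if (is.matrix(vb) && nrow(vb) == 1L && nrow(va) > 1L) {
    v <- va + matrix(vb, nrow(va), ncol(va), byrow = TRUE)
    emit(v, list(a, b), list(
      function(g) g,
      function(g) matrix(colSums(g), 1L)
    ))
  } else if (length(vb) == 1L && !is.matrix(vb)) {
    emit(va + vb, list(a), list(function(g) g))
  } else {
    emit(va + vb, list(a, b), list(function(g) g, function(g) g))
  }
}

op_sub <- function(a, b) op_add(a, op_scale(b, -1))

op_scale <- function(a, s) {
  emit(nval(a) * s, list(a), list(function(g) g * s))
}

op_mul <- function(a, b) {
  va <- nval(a); vb <- nval(b)
  emit(va * vb, list(a, b), list(
    function(g) g * vb,
    function(g) g * va
  ))
}

# multiply matrix a by the scalar value of 1x1 node/matrix s
op_mul_scalar <- function(a, s) {
  va <- nval(a); vs <- as.numeric(nval(s))
  emit(va * vs, list(a, s), list(
    function(g) g * vs,
    function(g) matrix(sum(g * va), 1L, 1L)
  ))
}

op_relu <- function(a) {
  va <- nval(a)
  emit(pmax(va, 0), list(a), list(function(g) g * (va > 0)))
}

op_gelu <- function(a) {
  va <- nval(a)
  emit(va * stats::pnorm(va), list(a), list(
    function(g) g * (stats::pnorm(va) + va * stats::dnorm(va))
  ))
}

# exp clamped above at `cap` (used for learned attention temperatures)
op_exp_clamp <- function(a, cap = 100) {
  va <- nval(a)
  ev <- exp(va)
  emit(pmin(ev, cap), list(a), list(function(g) g * ev * (ev < cap)))
}

op_softmax_rows <- function(a) {
  va <- nval(a)
  e <- exp(va - apply(va, 1L, max))
  y <- e / rowSums(e)
  emit(y, list(a), list(
    function(g) y * (g - rowSums(g * y))
  ))
}

op_logsoftmax_rows <- function(a) {
  va <- nval(a)
  m <- apply(va, 1L, max)
  lse <- m + log(rowSums(exp(va - m)))
  v <- va - lse
  sm <- exp(v)
  emit(v, list(a), list(
    function(g) g - sm * rowSums(g)
  ))
}

op_layernorm <- function(a, gamma, beta, eps = 1e-5) {
  va <- nval(a); vg <- nval(gamma)
  d <- ncol(va)
  mu <- rowMeans(va)
  xc <- va - mu
  va_r <- rowSums(xc * xc) / d
  inv <- 1 / sqrt(va_r + eps)
  xhat <- xc * inv
  gmat <- matrix(vg, nrow(va), d, byrow = TRUE)
  v <- xhat * gmat + matrix(nval(beta), nrow(va), d, byrow = TRUE)
  emit(v, list(a, gamma, beta), list(
    function(g) {
      dxh <- g * gmat
      (dxh - rowMeans(dxh) - xhat * rowMeans(dxh * xhat)) * inv
    },
    function(g) matrix(colSums(g * xhat), 1L),
    function(g) matrix(colSums(g), 1L)
  ))
}

op_l2norm_rows <- function(a, eps = 1e-8) {
  va <- nval(a)
  n <- sqrt(rowSums(va * va) + eps)
  y <- va / n
  emit(y, list(a), list(
    function(g) (g - y * rowSums(g * y)) / n
  ))
}

op_gather_rows <- function(a, idx) {
  va <- nval(a)
  emit(va[idx, , drop = FALSE], list(a), list(
    function(g) {
      z <- matrix(0, nrow(va), ncol(va))
      gs <- rowsum(g, idx)
      z[as.integer(rownames(gs)), ] <- gs
      z
    }
  ))
}

op_slice_cols <- function(a, from, to) {
  va <- nval(a)
  emit(va[, from:to, drop = FALSE], list(a), list(
    function(g) {
      z <- matrix(0, nrow(va), ncol(va))
      z[, from:to] <- g
      z
    }
  ))
}

op_cbind2 <- function(a, b) {
  va <- nval(a); vb <- nval(b)
  na <- ncol(va)
  emit(cbind(va, vb), list(a, b), list(
    function(g) g[, seq_len(na), drop = FALSE],
    function(g) g[, -seq_len(na), drop = FALSE]
  ))
}

op_cbind <- function(xs) Reduce(op_cbind2, xs)

op_t <- function(a) {
  emit(t(nval(a)), list(a), list(function(g) t(g)))
}

op_reshape <- function(a, nr, nc) {
  va <- nval(a)
  emit(matrix(as.vector(va), nr, nc), list(a), list(
    function(g) matrix(as.vector(g), nrow(va), ncol(va))
  ))
}

op_sum <- function(a) {
  va <- nval(a)
  emit(matrix(sum(va), 1L, 1L), list(a), list(
    function(g) matrix(as.numeric(g), nrow(va), ncol(va))
  ))
}

op_mean <- function(a) op_scale(op_sum(a), 1 / length(nval(a)))

# column means as a 1 x d row (token mean-pooling)
op_colmeans <- function(a) {
  va <- nval(a)
  n <- nrow(va)
  emit(matrix(colMeans(va), 1L), list(a), list(
    function(g) matrix(g, n, ncol(va), byrow = TRUE) / n
  ))
}

op_rbind2 <- function(a, b) {
  va <- nval(a); vb <- nval(b)
  na <- nrow(va)
  emit(rbind(va, vb), list(a, b), list(
    function(g) g[seq_len(na), , drop = FALSE],
    function(g) g[-seq_len(na), , drop = FALSE]
  ))
}

op_rbind <- function(xs) Reduce(op_rbind2, xs)
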