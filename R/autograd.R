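# Minimal reverse-mode autodiff on dense arrays.
#
# Feature maps are stored internally as base-R arrays laid out (H, W, C, B)
# (spatial fastest-varying, column-major), which makes im2col slices and
# per-channel broadcasting contiguous. A "variable" wraps a value plus an
# accumulated gradient in an environment, so gradients can be pushed into it
# by reference during the backward sweep. A "tape" records operation nodes in
# creation order; backward() replays them in reverse.

new_tape <- function() {
  t <- new.env(parent = emptyenv())
  t$nodes <- vector("list", 512L)
  t$n <- 0L
  t
}

tape_push <- function(tape, node) {
  n <- tape$n + 1L
  if (n > length(tape$nodes)) {
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  }
  tape$nodes[[n]] <- node
  tape$n <- n
  invisible(node)
}

#' @keywords internal
vr <- function(value, param = FALSE) {
  v <- new.env(parent = emptyenv())
  v$v <- value
  v$g <- NULL
  v$bw <- NULL
  v$param <- param
  class(v) <- "fdu_variable"
  v
}

# A node needs a gradient if it is a learnable parameter or an intermediate
# produced by a recorded op. Plain leaf inputs (images) are skipped.
needs_grad <- function(x) x$param || !is.null(x$bw)

acc_grad <- function(x, g) {
  if (!needs_grad(x)) return(invisible(NULL))
  if (is.null(x$g)) x$g <- g else x$g <- x$g + g
  invisible(NULL)
}

# Create an output node; record it (with its backward closure) when a tape is
# active. `bw` receives the output gradient and pushes into the parents.
make_node <- function(tape, value, bw) {
  out <- vr(value)
  if (!is.null(tape)) {
    out$bw <- bw
    tape_push(tape, out)
  }
  out
}

# Backward sweep from a scalar loss node.
backward <- function(tape, loss) {
  stopifnot(length(loss$v) == 1L)
  loss$g <- 1
  for (i in seq.int(tape$n, 1L)) {
    nd <- tape$nodes[[i]]
    if (!is.null(nd$g) && !is.null(nd$bw)) nd$bw(nd$g)
    nd$g <- NULL # free as we go
    tape$nodes[i] <- list(NULL)
  }
  tape$n <- 0L
  invisible(NULL)
}

zero_grads <- function(params) {
  for (p in params) p$g <- NULL
  invisible(NULL)
}

## ---- elementwise ops -------------------------------------------------------

op_elu <- function(tape, x, alpha = 1) {
  v <- x$v
  neg <- v < 0
  y <- v
  y[neg] <- alpha * (exp(v[neg]) - 1)
  make_node(tape, y, function(g) {
    d <- array(1, dim(v))
    d[neg] <- y[neg] + alpha # alpha * exp(v) on the negative side
    acc_grad(x, g * d)
  })
}

op_relu <- function(tape, x) {
  v <- x$v
  y <- pmax(v, 0)
  if (!is.null(dim(v))) dim(y) <- dim(v)
  make_node(tape, y, function(g) {
    g[v <= 0] <- 0
    acc_grad(x, g)
  })
}

op_gelu <- function(tape, x) {
  # exact (erf-based) GELU: x * pnorm(x)
  v <- x$v
  pv <- stats::pnorm(v)
  y <- v * pv
  make_node(tape, y, function(g) {
    acc_grad(x, g * (pv + v * stats::dnorm(v)))
  })
}

op_sigmoid <- function(tape, x) {
  s <- stats::plogis(x$v)
  if (!is.null(dim(x$v))) dim(s) <- dim(x$v)
  make_node(tape, s, function(g) acc_grad(x, g * s * (1 - s)))
}

op_add <- function(tape, a, b) {
  make_node(tape, a$v + b$v, function(g) {
    acc_grad(a, g)
    acc_grad(b, g)
  })
}

op_mul <- function(tape, a, b) {
  av <- a$v
  bv <- b$v
  make_node(tape, av * bv, function(g) {
    acc_grad(a, g * bv)
    acc_grad(b, g * av)
  })
}

op_scale <- function(tape, a, k) {
  make_node(tape, a$v * k, function(g) acc_grad(a, g * k))
}

## ---- shape/broadcast helpers ----------------------------------------------

# rep a per-channel vector over an (H, W, C, B) array layout
bc_ch <- function(vec, npos, B) rep(rep(vec, each = npos), times = B)

# per-channel sum over (H*W, B) of an (H, W, C, B) array
ch_sum <- function(a, npos, C, B) {
  cs <- colSums(matrix(a, npos)) # length C*B
  rowSums(matrix(cs, C, B))
}
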