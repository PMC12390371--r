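# Module infrastructure: a module is an environment holding learnable
# parameters (`params`, named list of variables), child modules (`children`),
# optional non-learnable buffers (`buffers`, e.g. batch-norm running
# statistics) and a forward function `fwd(self, x, ctx)` where
# ctx = list(tape =, training =).

new_module <- function(type, fwd = NULL, children = list(), params = list(),
                       buffers = NULL, ...) {
  m <- new.env(parent = emptyenv())
  m$type <- type
  m$children <- children
  m$params <- params
  m$buffers <- buffers
  m$fwd <- fwd
  extras <- list(...)
  for (nm in names(extras)) assign(nm, extras[[nm]], envir = m)
  class(m) <- "fdu_module"
  m
}

mod_fwd <- function(m, x, ctx) m$fwd(m, x, ctx)

#' Collect all learnable parameters of a module
#'
#' Walks the module tree and returns a named list of parameter variables,
#' with dot-separated path names.
#'
#' @param m a module (e.g. from [fr_block()] or [build_network()]).
#' @return named list of parameter variables.
#' @keywords internal
module_params <- function(m) {
  out <- list()
  if (length(m$params)) {
    ps <- m$params[!vapply(m$params, is.null, logical(1))]
    out <- ps
  }
  for (nm in names(m$children)) {
    ch <- m$children[[nm]]
    if (is.null(ch)) next
    cp <- module_params(ch)
    if (length(cp)) names(cp) <- paste(nm, names(cp), sep = ".")
    out <- c(out, cp)
  }
  out
}

#' Count trainable parameters
#'
#' Exact number of learnable scalars in a module (convolution weights and
#' biases, batch-norm scales and shifts, frequency-modulation weights).
#'
#' @param m a module.
#' @return integer count.
#' @export
#' @examples
#' count_trainable_params(vgg_block(64, 64)) # 74112
#' count_trainable_params(fr_block(64, 64))  # 33120
count_trainable_params <- function(m) {
  sum(vapply(module_params(m), function(p) length(p$v), numeric(1)))
}

## ---- state dict (checkpointing) ---------------------------------------------

state_dict <- function(m) {
  list(
    params = lapply(module_params(m), function(p) p$v),
    buffers = buffer_dict(m)
  )
}

buffer_dict <- function(m) {
  out <- list()
  if (!is.null(m$buffers)) out[["."]] <- m$buffers
  for (nm in names(m$children)) {
    ch <- m$children[[nm]]
    if (is.null(ch)) next
    bd <- buffer_dict(ch)
    if (length(bd)) names(bd) <- paste(nm, names(bd), sep = ".")
    out <- c(out, bd)
  }
  out
}

load_state_dict <- function(m, sd) {
  ps <- module_params(m)
  stopifnot(identical(sort(names(ps)), sort(names(sd$params))))
  for (nm in names(ps)) {
    stopifnot(length(ps[[nm]]$v) == length(sd$params[[nm]]))
    ps[[nm]]$v <- sd$params[[nm]]
  }
  set_buffers(m, sd$buffers, "")
  invisible(m)
}

set_buffers <- function(m, bd, prefix) {
  key <- if (prefix == "") "." else paste(prefix, ".", sep = ".")
  if (!is.null(m$buffers) && !is.null(bd[[key]])) m$buffers <- bd[[key]]
  for (cn in names(m$children)) {
    ch <- m$children[[cn]]
    if (is.null(ch)) next
    set_buffers(ch, bd, if (prefix == "") cn else paste(prefix, cn, sep = "."))
  }
  invisible(m)
}

## ---- primitive layers --------------------------------------------------------

# standard 2D convolution layer ("same" padding, stride 1)
layer_conv <- function(c_in, c_out, k = 1L, dilation = 1L, bias = TRUE,
                       init = c("he", "ones", "zeros"), gain = 1) {
  init <- match.arg(init)
  n_in <- k * k * c_in
  Wv <- switch(init,
    he = matrix(stats::rnorm(n_in * c_out, sd = gain * sqrt(2 / n_in)),
                n_in, c_out),
    ones = matrix(1, n_in, c_out),
    zeros = matrix(0, n_in, c_out)
  )
  params <- list(W = vr(Wv, param = TRUE))
  if (bias) params$b <- vr(numeric(c_out), param = TRUE)
  new_module("conv",
    fwd = function(self, x, ctx) {
      op_conv2d(ctx$tape, x, self$params$W, self$params$b, self$k,
                self$dilation)
    },
    params = params, k = as.integer(k), dilation = as.integer(dilation),
    c_in = c_in, c_out = c_out
  )
}

# depthwise k x k convolution (one filter per channel)
layer_dwconv <- function(c, k = 3L, bias = TRUE) {
  Wv <- matrix(stats::rnorm(k * k * c, sd = sqrt(2 / (k * k))), k * k, c)
  params <- list(W = vr(Wv, param = TRUE))
  if (bias) params$b <- vr(numeric(c), param = TRUE)
  new_module("dwconv",
    fwd = function(self, x, ctx) {
      op_dwconv2d(ctx$tape, x, self$params$W, self$params$b, self$k)
    },
    params = params, k = as.integer(k), channels = c
  )
}

# batch normalization (train: batch statistics; eval: running statistics)
layer_bn <- function(c, momentum = 0.1, eps = 1e-5) {
  new_module("bn",
    fwd = function(self, x, ctx) op_bn(ctx$tape, x, self, ctx$training),
    params = list(gamma = vr(rep(1, c), param = TRUE),
                  beta = vr(numeric(c), param = TRUE)),
    buffers = list(running_mean = numeric(c), running_var = rep(1, c)),
    momentum = momentum, eps = eps, channels = c
  )
}

# learnable half-spectrum amplitude weights for one patch scale
layer_freq_weights <- function(c, P) {
  new_module("freq",
    fwd = function(self, x, ctx) op_freq_filter(ctx$tape, x, self$params$w,
                                                self$P),
    params = list(w = vr(array(1, c(P, P %/% 2L + 1L, c)), param = TRUE)),
    P = as.integer(P), channels = c
  )
}

#' Run a module forward in inference mode
#'
#' Applies a module (block or full network) to a batch of feature maps using
#' the user-facing `(B, C, H, W)` array convention. Batch-norm layers use
#' their running statistics unless `training = TRUE` (in which case batch
#' statistics are used, as during optimization).
#'
#' @param m a module (e.g. from [fr_block()], [eap_module()],
#'   [build_network()]).
#' @param x numeric array `(B, C, H, W)`.
#' @param training logical; use batch statistics in normalization layers.
#' @return numeric array `(B, C_out, H, W)`.
#' @export
module_forward <- function(m, x, training = FALSE) {
  stopifnot(length(dim(x)) == 4L)
  xv <- vr(as_internal(x))
  ctx <- list(tape = NULL, training = training)
  as_external(mod_fwd(m, xv, ctx)$v)
}
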