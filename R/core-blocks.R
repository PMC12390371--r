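# Convolutional building blocks of the nested segmentation network.
#
# The residual feature reconstruction block (FRBlock) replaces the standard
# two-convolution unit of U-Net++. Its layout:
#
#   F1     = ELU(BN(Conv3x3(X)))              C_in  -> C_mid
#   F2     = ELU(Conv3x3(ELU(Conv1x1(F1))))   C_mid -> C_mid
#   Ffused = ELU(BN(Conv1x1([F1, F2])))       2*C_mid -> C_out
#   Y      = ELU(Ffused + Shortcut(X))
#
# where the shortcut is the identity when C_in = C_out and a 1x1 convolution
# otherwise. The serial 1x1/3x3 reconstruction path carries no batch norm; all
# convolutions carry biases. With C_mid = C_out / 2 the 64 -> 64 block has
# 33,120 parameters (0.0331 M), about half of the 74,112 (0.0741 M) of the
# two-convolution VGG-style block it replaces.

#' Residual feature reconstruction block (FRBlock)
#'
#' Builds the residual feature reconstruction block: a 3x3 convolution into a
#' reduced width `c_mid`, a serial 1x1 -> 3x3 reconstruction path, channel
#' concatenation of the two stages, a 1x1 fusion convolution to `c_out`, and a
#' residual connection (identity when `c_in == c_out`, 1x1 convolution
#' otherwise), with ELU activations and batch normalization after the first
#' and the fusion convolutions.
#'
#' @param c_in,c_out input/output channel counts.
#' @param c_mid internal width; defaults to `max(1, c_out %/% 2)`.
#' @param use_bias whether convolutions carry biases (default TRUE).
#' @return a module; apply it with [module_forward()].
#' @export
#' @examples
#' blk <- fr_block(64, 64)
#' count_trainable_params(blk) # 33120
fr_block <- function(c_in, c_out, c_mid = max(1L, c_out %/% 2L),
                     use_bias = TRUE) {
  stopifnot(c_in >= 1L, c_out >= 1L, c_mid >= 1L)
  children <- list(
    conv1 = layer_conv(c_in, c_mid, k = 3L, bias = use_bias),
    bn1 = layer_bn(c_mid),
    conv2 = layer_conv(c_mid, c_mid, k = 1L, bias = use_bias),
    conv3 = layer_conv(c_mid, c_mid, k = 3L, bias = use_bias),
    fuse = layer_conv(2L * c_mid, c_out, k = 1L, bias = use_bias),
    bn2 = layer_bn(c_out)
  )
  if (c_in != c_out) {
    children$shortcut <- layer_conv(c_in, c_out, k = 1L, bias = use_bias)
  }
  new_module("fr_block",
    fwd = function(self, x, ctx) {
      if (dim(x$v)[3] != self$c_in) {
        stop("input-contract error: block expects ", self$c_in,
             " channels, got ", dim(x$v)[3])
      }
      ch <- self$children
      tp <- ctx$tape
      f1 <- op_elu(tp, mod_fwd(ch$bn1, mod_fwd(ch$conv1, x, ctx), ctx))
      f2 <- op_elu(tp, mod_fwd(ch$conv3,
                               op_elu(tp, mod_fwd(ch$conv2, f1, ctx)), ctx))
      fused <- op_elu(tp, mod_fwd(ch$bn2,
                                  mod_fwd(ch$fuse,
                                          op_concat(tp, list(f1, f2)), ctx),
                                  ctx))
      sc <- if (is.null(ch$shortcut)) x else mod_fwd(ch$shortcut, x, ctx)
      op_elu(tp, op_add(tp, fused, sc))
    },
    children = children, c_in = c_in, c_out = c_out, c_mid = c_mid
  )
}

#' Two-convolution VGG-style block (U-Net++ baseline unit)
#'
#' Two successive (3x3 convolution, batch normalization, ReLU) stages mapping
#' `c_in -> c_out -> c_out`; the standard convolutional unit of U-Net++.
#'
#' @param c_in,c_out input/output channel counts.
#' @param use_bn include batch normalization (default TRUE).
#' @return a module; apply it with [module_forward()].
#' @export
#' @examples
#' count_trainable_params(vgg_block(64, 64))                  # 74112
#' count_trainable_params(vgg_block(64, 64, use_bn = FALSE))  # 73856
vgg_block <- function(c_in, c_out, use_bn = TRUE) {
  children <- list(conv1 = layer_conv(c_in, c_out, k = 3L))
  if (use_bn) children$bn1 <- layer_bn(c_out)
  children$conv2 <- layer_conv(c_out, c_out, k = 3L)
  if (use_bn) children$bn2 <- layer_bn(c_out)
  new_module("vgg_block",
    fwd = function(self, x, ctx) {
      if (dim(x$v)[3] != self$c_in) {
        stop("input-contract error: block expects ", self$c_in,
             " channels, got ", dim(x$v)[3])
      }
      ch <- self$children
      h <- mod_fwd(ch$conv1, x, ctx)
      if (!is.null(ch$bn1)) h <- mod_fwd(ch$bn1, h, ctx)
      h <- op_relu(ctx$tape, h)
      h <- mod_fwd(ch$conv2, h, ctx)
      if (!is.null(ch$bn2)) h <- mod_fwd(ch$bn2, h, ctx)
      op_relu(ctx$tape, h)
    },
    children = children, c_in = c_in, c_out = c_out
  )
}
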