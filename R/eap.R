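# Efficient attention pyramid (EAP): five-branch atrous spatial pyramid
# pooling whose fused output is gated by a directional (row/column) attention
# map, applied at the encoder bottleneck.
#
# ASPP branches: 1x1 conv; 3x3 atrous convs at dilations 6/12/18; global
# average pooling -> 1x1 conv -> broadcast. Each branch is followed by batch
# norm + ELU; the five outputs are concatenated to 5C channels.
#
# Attention gate: the 5C map is compressed back to C (1x1 conv + BN + ELU),
# average-pooled along width (per-row descriptors) and along height
# (per-column descriptors); the two descriptor sequences are concatenated
# along the spatial axis, passed through a shared 1x1 bottleneck convolution
# (channel reduction C/r), split back, mapped to C channels and squashed by a
# sigmoid each. The joint attention map is the rank-1 (outer) product of the
# per-row and per-column gates — literally a matrix multiplication of an
# H x 1 map by a 1 x W map — and the output is Fr * A + Fr.

aspp_branch <- function(c, k, dilation = 1L) {
  new_module("aspp_branch",
    fwd = function(self, x, ctx) {
      h <- mod_fwd(self$children$conv, x, ctx)
      h <- mod_fwd(self$children$bn, h, ctx)
      op_elu(ctx$tape, h)
    },
    children = list(conv = layer_conv(c, c, k = k, dilation = dilation),
                    bn = layer_bn(c))
  )
}

aspp_submodule <- function(channels, dilation_rates) {
  children <- list(b0 = aspp_branch(channels, k = 1L))
  for (i in seq_along(dilation_rates)) {
    children[[paste0("b", i)]] <-
      aspp_branch(channels, k = 3L, dilation = dilation_rates[i])
  }
  children$pool_conv <- layer_conv(channels, channels, k = 1L)
  children$pool_bn <- layer_bn(channels)
  new_module("aspp",
    fwd = function(self, x, ctx) {
      if (any(!is.finite(x$v))) stop("non-finite input to attention pyramid")
      tp <- ctx$tape
      d <- dim(x$v)
      ch <- self$children
      outs <- list(mod_fwd(ch$b0, x, ctx))
      for (i in seq_along(self$dilation_rates)) {
        outs[[i + 1L]] <- mod_fwd(ch[[paste0("b", i)]], x, ctx)
      }
      gp <- op_gap(tp, x)
      gp <- op_elu(tp, mod_fwd(ch$pool_bn, mod_fwd(ch$pool_conv, gp, ctx),
                               ctx))
      outs[[length(outs) + 1L]] <- op_expand_hw(tp, gp, d[1], d[2])
      op_concat(tp, outs)
    },
    children = children, channels = channels, dilation_rates = dilation_rates
  )
}

ema_submodule <- function(channels, reduction) {
  if (channels %% reduction != 0L) {
    stop("config error: channels (", channels,
         ") not divisible by attention reduction (", reduction, ")")
  }
  cr <- channels %/% reduction
  new_module("ema",
    fwd = function(self, x, ctx) {
      tp <- ctx$tape
      ch <- self$children
      fr <- op_elu(tp, mod_fwd(ch$bn_r, mod_fwd(ch$conv_r, x, ctx), ctx))
      d <- dim(fr$v)
      H <- d[1]; W <- d[2]
      fh <- op_mean_w(tp, fr)                       # (H, 1, C, B)
      fw <- op_transpose_hw(tp, op_mean_h(tp, fr))  # (W, 1, C, B)
      tt <- op_concat(tp, list(fh, fw), axis = 1L)  # (H + W, 1, C, B)
      tt <- op_elu(tp, mod_fwd(ch$conv_sh, tt, ctx))
      sp <- op_split(tp, tt, c(H, W), axis = 1L)
      gh <- op_sigmoid(tp, mod_fwd(ch$conv_h, sp[[1]], ctx))
      gw <- op_sigmoid(tp, mod_fwd(ch$conv_w, sp[[2]], ctx))
      gw <- op_transpose_hw(tp, gw)                 # (1, W, C, B)
      att <- op_mul(tp, op_expand_w(tp, gh, W), op_expand_h(tp, gw, H))
      op_add(tp, op_mul(tp, fr, att), fr)
    },
    children = list(
      conv_r = layer_conv(5L * channels, channels, k = 1L),
      bn_r = layer_bn(channels),
      conv_sh = layer_conv(channels, cr, k = 1L),
      conv_h = layer_conv(cr, channels, k = 1L),
      conv_w = layer_conv(cr, channels, k = 1L)
    ),
    channels = channels, reduction = reduction
  )
}

#' Efficient attention pyramid (EAP) module
#'
#' Five-branch atrous spatial pyramid pooling (1x1 convolution, three 3x3
#' atrous convolutions at the given dilation rates, and an image-pooling
#' branch) fused by a directional attention gate built from row/column average
#' pooling and a rank-1 attention map. Input and output channel counts are
#' equal, so the module is a drop-in enhancement at the encoder bottleneck.
#'
#' @param channels number of input (= output) channels.
#' @param dilation_rates dilation factors of the 3x3 branches
#'   (default `c(6, 12, 18)`).
#' @param reduction channel-compression divisor of the attention bottleneck
#'   (default 16); `channels` must be divisible by it.
#' @return a module; apply it with [module_forward()]. The `aspp` and `ema`
#'   children expose the two stages separately.
#' @export
eap_module <- function(channels, dilation_rates = c(6L, 12L, 18L),
                       reduction = 16L) {
  new_module("eap",
    fwd = function(self, x, ctx) {
      mod_fwd(self$children$ema, mod_fwd(self$children$aspp, x, ctx), ctx)
    },
    children = list(
      aspp = aspp_submodule(channels, as.integer(dilation_rates)),
      ema = ema_submodule(channels, as.integer(reduction))
    ),
    channels = channels
  )
}
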