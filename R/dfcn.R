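# Dynamic frequency context network (DFCN): gated local feature extraction
# followed by multi-scale patchwise FFT filtering with learnable amplitude
# weights, deployed after the blocks of the deep decoder nodes.
#
#   X_ext      = Conv1x1(X)            C -> 2C
#   X1, X2     = Split(X_ext)          C each
#   X_local    = GELU(DW3x3(X1)) * DW3x3(X2)
#   X~(s)      = IFFT2( FFT2(patches_P_s(X_local)) * W_f(s) ),  P_s in {4,8,16}
#   Y          = Conv1x1([X~(1), X~(2), X~(3)])   3C -> C
#
# The three scales filter the same local map in parallel. All frequency
# weights are initialized to 1, so at initialization the whole frequency path
# is the identity and the module is a purely local operator.

#' Dynamic frequency context network (DFCN) module
#'
#' Channel expansion and split, a GELU-gated depthwise local path, parallel
#' patchwise frequency filtering at patch sizes 4/8/16 with learnable
#' amplitude weights (see [freq_filter_scale()] for the filtering primitive),
#' channel concatenation and a 1x1 projection back to the input width. Input
#' and output shapes are equal, so the module is a drop-in enhancement after
#' a decoder block. Feature maps whose sides are not multiples of a patch size
#' are reflect-padded before tiling and cropped after the inverse transform.
#'
#' @param channels number of input (= output) channels.
#' @param patch_sizes patch side lengths of the frequency pyramid
#'   (default `c(4, 8, 16)`).
#' @return a module; apply it with [module_forward()].
#' @export
dfcn_module <- function(channels, patch_sizes = c(4L, 8L, 16L)) {
  children <- list(
    expand = layer_conv(channels, 2L * channels, k = 1L),
    dw1 = layer_dwconv(channels),
    dw2 = layer_dwconv(channels),
    # attenuated initialization: the GELU-gated product multiplies feature
    # magnitudes, so a unit-gain projection would inflate the activation
    # scale of every decoder stage it feeds at the start of training
    proj = layer_conv(length(patch_sizes) * channels, channels, k = 1L,
                      gain = 0.2)
  )
  for (i in seq_along(patch_sizes)) {
    children[[paste0("freq", i)]] <-
      layer_freq_weights(channels, as.integer(patch_sizes[i]))
  }
  new_module("dfcn",
    fwd = function(self, x, ctx) {
      tp <- ctx$tape
      ch <- self$children
      xl <- dfcn_local(self, x, ctx)
      outs <- lapply(seq_along(self$patch_sizes), function(i) {
        mod_fwd(ch[[paste0("freq", i)]], xl, ctx)
      })
      mod_fwd(ch$proj, op_concat(tp, outs), ctx)
    },
    children = children, channels = channels,
    patch_sizes = as.integer(patch_sizes)
  )
}

# expansion + split + gated depthwise local path (Eq. 16-18 stage)
dfcn_local <- function(self, x, ctx) {
  tp <- ctx$tape
  ch <- self$children
  C <- self$channels
  xe <- mod_fwd(ch$expand, x, ctx)
  sp <- op_split(tp, xe, c(C, C))
  d1 <- mod_fwd(ch$dw1, sp[[1]], ctx)
  d2 <- mod_fwd(ch$dw2, sp[[2]], ctx)
  op_mul(tp, op_gelu(tp, d1), d2)
}
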