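# Model profiling: exact trainable-parameter counts and analytic FLOPs.
# FLOPs convention: 2 operations per multiply-accumulate, convolutions and
# linear maps only (bias additions, normalization, activations and FFTs are
# not counted); the convention is recorded in the report.

conv_flops <- function(k2, c_in, c_out, npix) 2 * k2 * c_in * c_out * npix

block_flops <- function(use_frblock, c_in, c_out, npix) {
  if (use_frblock) {
    c_mid <- max(1L, c_out %/% 2L)
    f <- conv_flops(9, c_in, c_mid, npix) + conv_flops(1, c_mid, c_mid, npix) +
      conv_flops(9, c_mid, c_mid, npix) +
      conv_flops(1, 2L * c_mid, c_out, npix)
    if (c_in != c_out) f <- f + conv_flops(1, c_in, c_out, npix)
    f
  } else {
    conv_flops(9, c_in, c_out, npix) + conv_flops(9, c_out, c_out, npix)
  }
}

eap_flops <- function(C, H, W, reduction = 16L) {
  npix <- H * W
  cr <- C %/% reduction
  conv_flops(1, C, C, npix) + 3 * conv_flops(9, C, C, npix) +
    conv_flops(1, C, C, 1) + conv_flops(1, 5L * C, C, npix) +
    conv_flops(1, C, cr, H + W) + 2 * conv_flops(1, cr, C, H + W)
}

dfcn_flops <- function(C, npix) {
  conv_flops(1, C, 2L * C, npix) + 2 * (2 * 9 * C * npix) +
    conv_flops(1, 3L * C, C, npix)
}

#' Analytic FLOPs of a network configuration
#'
#' Counts 2 operations per multiply-accumulate for convolutions and linear
#' maps only, at the given input resolution.
#'
#' @param widths,in_channels,out_channels,use_frblock,use_eap,use_dfcn,dfcn_nodes
#'   as in [build_network()].
#' @param input_size input side in pixels (default 256).
#' @return total FLOPs (numeric).
#' @export
network_flops <- function(widths = c(32L, 64L, 128L, 256L, 512L),
                          in_channels = 3L, out_channels = 1L,
                          use_frblock = TRUE, use_eap = TRUE, use_dfcn = TRUE,
                          dfcn_nodes = c("x0_2", "x0_3", "x0_4"),
                          input_size = 256L) {
  depth <- 4L
  total <- 0
  for (i in 0:depth) {
    npix <- (input_size / 2^i)^2
    for (j in 0:(depth - i)) {
      c_in <- if (j == 0L) {
        if (i == 0L) in_channels else widths[i]
      } else {
        j * widths[i + 1L] + widths[i + 2L]
      }
      total <- total + block_flops(use_frblock, c_in, widths[i + 1L], npix)
    }
  }
  if (use_eap) {
    s <- input_size / 2^depth
    total <- total + eap_flops(widths[5L], s, s)
  }
  if (use_dfcn) {
    for (nd in dfcn_nodes) {
      row <- as.integer(sub("x(\\d)_\\d", "\\1", nd))
      total <- total + dfcn_flops(widths[row + 1L], (input_size / 2^row)^2)
    }
  }
  total + conv_flops(1, widths[1L], out_channels, input_size^2)
}

#' Profile model components and configurations
#'
#' Builds each component at the reference 64-channel setting plus the baseline
#' U-Net++ and the configured network, and reports exact trainable-parameter
#' counts (integer and millions) and analytic FLOPs at the given input size.
#' Profiling is independent of random seeds and of training state.
#'
#' @param widths,in_channels,out_channels,use_frblock,use_eap,use_dfcn,dfcn_nodes
#'   network configuration, as in [build_network()].
#' @param input_size input side in pixels for the FLOPs column (default 256).
#' @return data frame with columns `component`, `params`, `params_M`,
#'   `flops_G` (NA for single blocks); the FLOPs convention is attached as the
#'   `flops_convention` attribute and printed in reports.
#' @export
#' @examples
#' prof <- cmd_profile()
#' subset(prof, component == "unetpp_baseline")$params_M # 9.16
cmd_profile <- function(widths = c(32L, 64L, 128L, 256L, 512L),
                        in_channels = 3L, out_channels = 1L,
                        use_frblock = TRUE, use_eap = TRUE, use_dfcn = TRUE,
                        dfcn_nodes = c("x0_2", "x0_3", "x0_4"),
                        input_size = 256L) {
  rows <- list()
  add <- function(component, params, flops = NA_real_) {
    rows[[length(rows) + 1L]] <<- data.frame(
      component = component, params = params,
      params_M = round(params / 1e6, 4), flops_G = round(flops / 1e9, 4),
      stringsAsFactors = FALSE)
  }
  add("vggblock_64_64", count_trainable_params(vgg_block(64L, 64L)))
  add("frblock_64_64", count_trainable_params(fr_block(64L, 64L)))
  add("eap_64", count_trainable_params(eap_module(64L)))
  add("dfcn_64", count_trainable_params(dfcn_module(64L)))
  base <- build_network(widths, in_channels, out_channels,
                        use_frblock = FALSE, use_eap = FALSE,
                        use_dfcn = FALSE, seed = 0L)
  add("unetpp_baseline", count_trainable_params(base),
      network_flops(widths, in_channels, out_channels, FALSE, FALSE, FALSE,
                    input_size = input_size))
  net <- build_network(widths, in_channels, out_channels, use_frblock,
                       use_eap, use_dfcn, dfcn_nodes, seed = 0L)
  add("configured_network", count_trainable_params(net),
      network_flops(widths, in_channels, out_channels, use_frblock, use_eap,
                    use_dfcn, dfcn_nodes, input_size))
  out <- do.call(rbind, rows)
  attr(out, "flops_convention") <-
    "2 ops per multiply-accumulate; convolutions and linear maps only"
  attr(out, "input_size") <- input_size
  out
}
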