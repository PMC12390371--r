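# FED-UNet++ assembly: the nested U-Net++ grid of nodes X^{i,j} (0 <= i+j <= 4)
# where node X^{i,j} receives the channel concatenation of all X^{i,k} (k < j)
# plus the 2x bilinear upsampling of X^{i+1,j-1}; the encoder spine downsamples
# by 2x2 max pooling. FRBlocks replace all convolution units, the efficient
# attention pyramid sits after the bottleneck node X^{4,0}, and the dynamic
# frequency context network follows the deep decoder nodes X^{0,2}..X^{0,4}.
# A single 1x1 head on X^{0,4} produces the logits.

node_name <- function(i, j) sprintf("x%d_%d", i, j)

#' Build the segmentation network
#'
#' Constructs the nested U-Net++ grid with the configured block type and
#' enhancement modules. With all three `use_*` flags off this is the plain
#' U-Net++ baseline (9,163,329 parameters at the default widths, i.e. 9.16 M);
#' with all on it is the full FED-UNet++.
#'
#' @param widths channel widths per depth, strictly doubling, length 5
#'   (default `c(32, 64, 128, 256, 512)`).
#' @param in_channels input image channels (default 3; grayscale slices are
#'   replicated to three channels on loading).
#' @param out_channels output channels of the logit head (default 1).
#' @param use_frblock replace the VGG-style blocks by FRBlocks (default TRUE).
#' @param use_eap insert the efficient attention pyramid after the bottleneck
#'   node (default TRUE).
#' @param use_dfcn apply the dynamic frequency context network after the nodes
#'   in `dfcn_nodes` (default TRUE).
#' @param dfcn_nodes decoder node names receiving a DFCN
#'   (default `c("x0_2", "x0_3", "x0_4")`).
#' @param seed optional RNG seed for weight initialization.
#' @return a network module. Apply with [module_forward()] (returns logits) or
#'   [predict_mask()]; persist with [save_checkpoint()].
#' @export
#' @examples
#' net <- build_network(widths = c(8, 16, 32, 64, 128), use_eap = FALSE,
#'                      use_dfcn = FALSE, seed = 1)
#' x <- array(rnorm(1 * 3 * 32 * 32), c(1, 3, 32, 32))
#' dim(module_forward(net, x)) # 1 1 32 32
build_network <- function(widths = c(32L, 64L, 128L, 256L, 512L),
                          in_channels = 3L, out_channels = 1L,
                          use_frblock = TRUE, use_eap = TRUE,
                          use_dfcn = TRUE,
                          dfcn_nodes = c("x0_2", "x0_3", "x0_4"),
                          seed = NULL) {
  widths <- as.integer(widths)
  if (length(widths) != 5L) stop("config error: `widths` must have length 5")
  if (any(widths[-1] != 2L * widths[-5])) {
    stop("config error: `widths` must double at each depth")
  }
  depth <- 4L
  all_nodes <- unlist(lapply(0:depth, function(i) {
    vapply(0:(depth - i), function(j) node_name(i, j), character(1))
  }))
  if (use_dfcn && !all(dfcn_nodes %in% all_nodes)) {
    stop("config error: unknown node name(s): ",
         paste(setdiff(dfcn_nodes, all_nodes), collapse = ", "))
  }
  cfg <- list(widths = widths, in_channels = in_channels,
              out_channels = out_channels, use_frblock = use_frblock,
              use_eap = use_eap, use_dfcn = use_dfcn,
              dfcn_nodes = dfcn_nodes)
  make_block <- function(c_in, c_out) {
    if (use_frblock) fr_block(c_in, c_out) else vgg_block(c_in, c_out)
  }
  build <- function() {
    children <- list()
    for (i in 0:depth) {
      for (j in 0:(depth - i)) {
        c_in <- if (j == 0L) {
          if (i == 0L) in_channels else widths[i]
        } else {
          j * widths[i + 1L] + widths[i + 2L]
        }
        children[[node_name(i, j)]] <- make_block(c_in, widths[i + 1L])
      }
    }
    if (use_eap) children$eap <- eap_module(widths[5L])
    if (use_dfcn) {
      for (nd in dfcn_nodes) {
        row <- as.integer(sub("x(\\d)_\\d", "\\1", nd))
        children[[paste0("dfcn_", nd)]] <- dfcn_module(widths[row + 1L])
      }
    }
    # zero-initialized head: the untrained network outputs logit 0
    # (probability 0.5) everywhere, keeping the initial loss at its natural
    # scale regardless of the activation magnitudes of the enhancement modules
    children$head <- layer_conv(widths[1L], out_channels, k = 1L,
                                init = "zeros")
    children
  }
  children <- if (is.null(seed)) build() else with_seed(seed, build())
  new_module("fed_unetpp",
    fwd = function(self, x, ctx) {
      d <- dim(x$v)
      if (d[3] != self$config$in_channels) {
        stop("input-contract error: network expects ",
             self$config$in_channels, " channels, got ", d[3])
      }
      if (d[1] %% 16L != 0L || d[2] %% 16L != 0L) {
        stop("input-contract error: spatial size must be divisible by 16")
      }
      tp <- ctx$tape
      ch <- self$children
      use_dfcn <- self$config$use_dfcn
      X <- vector("list", depth + 1L)
      for (i in 0:depth) X[[i + 1L]] <- vector("list", depth + 1L)
      # encoder spine
      for (i in 0:depth) {
        inp <- if (i == 0L) x else op_maxpool2(tp, X[[i]][[1L]])
        X[[i + 1L]][[1L]] <- mod_fwd(ch[[node_name(i, 0L)]], inp, ctx)
      }
      if (self$config$use_eap) {
        X[[depth + 1L]][[1L]] <- mod_fwd(ch$eap, X[[depth + 1L]][[1L]], ctx)
      }
      # nested decoder
      for (j in 1:depth) {
        for (i in 0:(depth - j)) {
          skips <- X[[i + 1L]][seq_len(j)]
          up <- op_upsample2(tp, X[[i + 2L]][[j]])
          h <- mod_fwd(ch[[node_name(i, j)]],
                       op_concat(tp, c(skips, list(up))), ctx)
          nd <- node_name(i, j)
          if (use_dfcn && nd %in% self$config$dfcn_nodes) {
            h <- mod_fwd(ch[[paste0("dfcn_", nd)]], h, ctx)
          }
          X[[i + 1L]][[j + 1L]] <- h
        }
      }
      mod_fwd(ch$head, X[[1L]][[depth + 1L]], ctx)
    },
    children = children, config = cfg
  )
}

#' Predict binary masks from images
#'
#' Runs the network in inference mode, applies the sigmoid to the logits and
#' thresholds the probabilities (`>= threshold`, so a probability map that is
#' exactly at the threshold maps to foreground).
#'
#' @param net network module from [build_network()] or [load_checkpoint()].
#' @param images numeric array `(B, C, H, W)` with intensities in `[0, 1]`.
#' @param threshold probability cutoff in (0, 1), default 0.5.
#' @return integer array `(B, H, W)` of 0/1 masks.
#' @export
predict_mask <- function(net, images, threshold = 0.5) {
  stopifnot(threshold > 0, threshold < 1)
  logits <- module_forward(net, images)
  prob <- stats::plogis(logits)
  mask <- (prob >= threshold) + 0L
  array(mask[, 1L, , ], dim(mask)[c(1L, 3L, 4L)])
}

#' Save / load a network checkpoint
#'
#' A checkpoint is a single RDS file holding the configuration that built the
#' network, all learnable parameter values, normalization running statistics,
#' and optional metadata.
#'
#' @param net network module.
#' @param path file path of the checkpoint.
#' @param extra optional named list of metadata (stored verbatim).
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint`
#'   returns a rebuilt network with the stored weights.
#' @export
save_checkpoint <- function(net, path, extra = list()) {
  saveRDS(list(config = net$config, state = state_dict(net), extra = extra),
          path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  net <- do.call(build_network, ck$config)
  load_state_dict(net, ck$state)
  net$checkpoint_extra <- ck$extra
  net
}
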