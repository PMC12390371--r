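# Training loop: Adam with L2 weight decay and cosine-annealed learning rate,
# minimizing the compound BCE + Dice loss. All randomness (initialization,
# shuffling) is seed-controlled.

#' Cosine annealing learning-rate schedule
#'
#' `lr(e) = lr_min + 0.5 * (lr_init - lr_min) * (1 + cos(pi * e / epochs))`,
#' so `lr(0) = lr_init` and `lr(epochs) = lr_min` exactly.
#'
#' @param epoch 0-based epoch index.
#' @param epochs total number of epochs.
#' @param lr_init,lr_min initial and minimum learning rates (defaults 1e-3 and
#'   1e-5).
#' @return learning rate at `epoch`.
#' @export
#' @examples
#' cosine_lr(0, 300)   # 1e-3
#' cosine_lr(300, 300) # 1e-5
cosine_lr <- function(epoch, epochs, lr_init = 1e-3, lr_min = 1e-5) {
  stopifnot(lr_min < lr_init)
  lr_min + 0.5 * (lr_init - lr_min) * (1 + cos(pi * epoch / epochs))
}

# one Adam update over a named list of parameter variables; optimizer moments
# live on the variables themselves
adam_step <- function(params, lr, t, beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                      weight_decay = 0) {
  for (p in params) {
    if (is.null(p$g)) next
    g <- p$g
    if (weight_decay > 0) g <- g + weight_decay * p$v
    if (is.null(p$opt_m)) {
      p$opt_m <- g * 0
      p$opt_v <- g * 0
    }
    p$opt_m <- beta1 * p$opt_m + (1 - beta1) * g
    p$opt_v <- beta2 * p$opt_v + (1 - beta2) * g * g
    mh <- p$opt_m / (1 - beta1^t)
    vh <- p$opt_v / (1 - beta2^t)
    p$v <- p$v - lr * mh / (sqrt(vh) + eps)
  }
  invisible(NULL)
}

#' Default training configuration
#'
#' The reference optimization protocol: Adam, initial learning rate 1e-3
#' cosine-annealed to 1e-5, weight decay 1e-4, 300 epochs, batch size 16,
#' BCE/Dice loss weights 0.5/0.5, with flip/rotation augmentation available.
#'
#' @param ... overrides of individual fields.
#' @return named list of training settings.
#' @export
train_config <- function(...) {
  cfg <- list(epochs = 300L, batch_size = 16L, lr_init = 1e-3, lr_min = 1e-5,
              weight_decay = 1e-4, w_bce = 0.5, w_dice = 0.5, seed = 1L,
              augment_flip = FALSE, augment_rot90 = FALSE)
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}

# stack a list of (H, W, 3) images / (H, W) masks into internal batch arrays
stack_batch <- function(images, masks, idx) {
  H <- dim(images[[idx[1]]])[1]
  W <- dim(images[[idx[1]]])[2]
  B <- length(idx)
  x <- array(0, c(H, W, 3L, B))
  t <- array(0, c(H, W, 1L, B))
  for (k in seq_along(idx)) {
    x[, , , k] <- images[[idx[k]]]
    t[, , 1L, k] <- masks[[idx[k]]]
  }
  list(x = x, t = t)
}

rot90s <- function(a, k) {
  # rotate the first two axes of an (H, W, ...) array by k * 90 degrees
  k <- k %% 4L
  if (k == 0L) return(a)
  for (i in seq_len(k)) {
    perm <- c(2L, 1L, seq_along(dim(a))[-(1:2)])
    a <- aperm(a, perm)
    idx <- rev(seq_len(dim(a)[1]))
    a <- if (length(dim(a)) == 3L) a[idx, , , drop = FALSE]
         else a[idx, , drop = FALSE]
  }
  a
}

augment_pair <- function(img, msk, cfg) {
  if (isTRUE(cfg$augment_flip) && stats::runif(1) < 0.5) {
    img <- img[, rev(seq_len(dim(img)[2])), , drop = FALSE]
    msk <- msk[, rev(seq_len(ncol(msk)))]
  }
  if (isTRUE(cfg$augment_rot90)) {
    k <- sample(0:3, 1)
    img <- rot90s(img, k)
    msk <- rot90s(msk, k)
  }
  list(img = img, msk = msk)
}

#' Train a network on an in-memory dataset
#'
#' Optimizes the compound BCE + Dice loss with Adam under a cosine-annealed
#' learning rate. Aborts with a diagnostic if the loss becomes non-finite.
#'
#' @param net network from [build_network()].
#' @param images list of `(H, W, 3)` arrays in `[0, 1]`.
#' @param masks list of binary `(H, W)` matrices.
#' @param config list from [train_config()].
#' @param val_images,val_masks optional validation set; per-epoch validation
#'   IoU is logged and the best-validation weights are reported.
#' @param verbose print per-epoch progress.
#' @return list with `net`, `log` (data frame: epoch, lr, train_loss,
#'   val_iou) and `best_epoch`.
#' @export
train_network <- function(net, images, masks, config = train_config(),
                          val_images = NULL, val_masks = NULL,
                          verbose = FALSE) {
  stopifnot(length(images) == length(masks), length(images) >= 1L)
  params <- module_params(net)
  n <- length(images)
  log <- data.frame(epoch = integer(0), lr = numeric(0),
                    train_loss = numeric(0), val_iou = numeric(0))
  best_iou <- -Inf
  best_epoch <- NA_integer_
  best_state <- NULL
  step <- 0L
  with_seed(config$seed, {
    for (epoch in seq_len(config$epochs)) {
      lr <- cosine_lr(epoch - 1L, config$epochs, config$lr_init,
                      config$lr_min)
      ord <- sample.int(n)
      losses <- numeric(0)
      for (start in seq(1L, n, by = config$batch_size)) {
        idx <- ord[start:min(start + config$batch_size - 1L, n)]
        imgs_b <- images[idx]
        msks_b <- masks[idx]
        if (isTRUE(config$augment_flip) || isTRUE(config$augment_rot90)) {
          for (k in seq_along(idx)) {
            au <- augment_pair(imgs_b[[k]], msks_b[[k]], config)
            imgs_b[[k]] <- au$img
            msks_b[[k]] <- au$msk
          }
        }
        bt <- stack_batch(imgs_b, msks_b, seq_along(idx))
        tape <- new_tape()
        ctx <- list(tape = tape, training = TRUE)
        logits <- mod_fwd(net, vr(bt$x), ctx)
        loss <- op_bce_dice(tape, logits, bt$t, config$w_bce, config$w_dice)
        if (!is.finite(loss$v)) {
          stop("training aborted: non-finite loss at epoch ", epoch)
        }
        zero_grads(params)
        backward(tape, loss)
        step <- step + 1L
        adam_step(params, lr, step, weight_decay = config$weight_decay)
        losses <- c(losses, loss$v)
      }
      val_iou <- NA_real_
      if (!is.null(val_images) && length(val_images) > 0L) {
        ev <- evaluate_network(net, val_images, val_masks, with_hd95 = FALSE)
        val_iou <- mean(ev$iou)
        if (val_iou > best_iou) {
          best_iou <- val_iou
          best_epoch <- epoch
          best_state <- state_dict(net)
        }
      }
      log <- rbind(log, data.frame(epoch = epoch, lr = lr,
                                   train_loss = mean(losses),
                                   val_iou = val_iou))
      if (verbose) {
        message(sprintf("epoch %3d  lr %.2e  loss %.4f  val IoU %s", epoch,
                        lr, mean(losses),
                        ifelse(is.na(val_iou), "-", sprintf("%.3f", val_iou))))
      }
    }
  })
  if (!is.null(best_state)) load_state_dict(net, best_state)
  list(net = net, log = log, best_epoch = best_epoch)
}

#' Evaluate a network on an image/mask set
#'
#' Predicts a binary mask per image (threshold 0.5) and computes the overlap
#' metrics and (optionally) HD95 per image.
#'
#' @param net network module.
#' @param images list of `(H, W, 3)` arrays in `[0, 1]`.
#' @param masks list of binary `(H, W)` matrices.
#' @param threshold probability cutoff (default 0.5).
#' @param with_hd95 also compute HD95 per image (default TRUE).
#' @param ids optional image identifiers for the report.
#' @return data frame, one row per image.
#' @export
evaluate_network <- function(net, images, masks, threshold = 0.5,
                             with_hd95 = TRUE, ids = NULL) {
  n <- length(images)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    img <- images[[i]]
    x <- array(aperm(img, c(3L, 1L, 2L)), c(1L, dim(img)[3], dim(img)[1],
                                            dim(img)[2]))
    pred <- predict_mask(net, x, threshold)
    pm <- matrix(pred[1L, , ], dim(img)[1], dim(img)[2])
    met <- segmentation_metrics(pm, masks[[i]], with_hd95 = with_hd95)
    rows[[i]] <- as.data.frame(as.list(met))
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    nm <- c("iou", "dice", "recall", "precision", "accuracy")
    if (with_hd95) nm <- c(nm, "hd95")
    out <- as.data.frame(matrix(numeric(0), 0L, length(nm),
                                dimnames = list(NULL, nm)))
  }
  ids <- ids %||% names(images) %||% as.character(seq_len(n))
  if (nrow(out) > 0L) out <- cbind(data.frame(id = ids), out)
  out
}
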