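# Evaluation metrics for binary segmentation: the pixel-count overlap metrics
#
#   IoU = TP / (TP + FP + FN)          Dice      = 2 TP / (2 TP + FP + FN)
#   Recall = TP / (TP + FN)            Precision = TP / (TP + FP)
#   Accuracy = (TP + TN) / (TP + TN + FP + FN)
#
# and the 95th-percentile Hausdorff boundary distance
#
#   HD95(A, B) = max( P95_{a in A} min_{b in B} ||a - b||,
#                     P95_{b in B} min_{a in A} ||a - b|| )
#
# with boundaries extracted as foreground pixels having at least one
# background 4-neighbor (pixels on the image border count as adjacent to
# background), and the percentile taken with linear interpolation between
# order statistics.

check_binary_pair <- function(pred, truth) {
  if (!identical(dim(pred), dim(truth)) || length(pred) != length(truth)) {
    stop("`pred` and `truth` must have identical shapes")
  }
  if (!all(pred %in% c(0, 1)) || !all(truth %in% c(0, 1))) {
    stop("masks must be strictly binary (0/1)")
  }
}

#' Pixel confusion counts
#'
#' Exhaustive partition of the pixels of a predicted and a reference binary
#' mask into true/false positives/negatives.
#'
#' @param pred,truth binary (0/1) arrays of identical shape.
#' @return named numeric vector `c(TP, FP, FN, TN)`; the four counts sum to
#'   the number of pixels.
#' @export
#' @examples
#' p <- matrix(c(1, 0, 0, 1, 1, 0, 0, 0, 0), 3, byrow = TRUE)
#' t <- matrix(c(1, 0, 0, 0, 1, 0, 0, 1, 0), 3, byrow = TRUE)
#' confusion_counts(p, t) # TP 2, FP 1, FN 1, TN 5
confusion_counts <- function(pred, truth) {
  check_binary_pair(pred, truth)
  tp <- sum(pred == 1 & truth == 1)
  fp <- sum(pred == 1 & truth == 0)
  fn <- sum(pred == 0 & truth == 1)
  tn <- sum(pred == 0 & truth == 0)
  c(TP = tp, FP = fp, FN = fn, TN = tn)
}

metrics_from_counts <- function(tp, fp, fn, tn) {
  pos_union <- tp + fp + fn
  iou <- if (pos_union == 0) 1 else tp / pos_union
  dice <- if (pos_union == 0) 1 else 2 * tp / (2 * tp + fp + fn)
  recall <- if (tp + fn == 0) 1 else tp / (tp + fn)
  # zero predicted foreground against a nonempty reference: precision 0
  # (pessimistic convention; avoids 0/0)
  precision <- if (tp + fp == 0) {
    if (fn == 0) 1 else 0
  } else {
    tp / (tp + fp)
  }
  accuracy <- (tp + tn) / (tp + fp + fn + tn)
  c(iou = iou, dice = dice, recall = recall, precision = precision,
    accuracy = accuracy)
}

#' Segmentation overlap metrics
#'
#' Computes IoU, Dice, recall, precision and accuracy from the confusion
#' counts, plus (optionally) the 95th-percentile Hausdorff distance. The
#' degenerate empty-vs-empty case is defined as perfect agreement
#' (IoU = Dice = 1).
#'
#' @param pred,truth binary (0/1) arrays of identical shape.
#' @param with_hd95 also compute [hd95()] (default TRUE; `NA` when either
#'   mask is empty).
#' @return named numeric vector with elements `iou`, `dice`, `recall`,
#'   `precision`, `accuracy` and (optionally) `hd95`.
#' @export
segmentation_metrics <- function(pred, truth, with_hd95 = TRUE) {
  cc <- confusion_counts(pred, truth)
  out <- metrics_from_counts(cc[["TP"]], cc[["FP"]], cc[["FN"]], cc[["TN"]])
  if (with_hd95) {
    h <- suppressWarnings(hd95(pred, truth))
    out <- c(out, hd95 = unname(h))
  }
  out
}

# boundary pixels: foreground with >= 1 background 4-neighbor (outside the
# image counts as background); returns an n x 2 matrix of (row, col)
boundary_points <- function(mask) {
  m <- as.matrix(mask)
  H <- nrow(m); W <- ncol(m)
  pad <- matrix(0, H + 2L, W + 2L)
  pad[2:(H + 1L), 2:(W + 1L)] <- m
  core <- pad[2:(H + 1L), 2:(W + 1L)]
  nb_bg <- (pad[1:H, 2:(W + 1L)] == 0) | (pad[3:(H + 2L), 2:(W + 1L)] == 0) |
    (pad[2:(H + 1L), 1:W] == 0) | (pad[2:(H + 1L), 3:(W + 2L)] == 0)
  which(core == 1 & nb_bg, arr.ind = TRUE)
}

directed_p95 <- function(A, B) {
  # 95th percentile (linear interpolation) of nearest-neighbor distances A -> B
  d2 <- outer(A[, 1], B[, 1], "-")^2 + outer(A[, 2], B[, 2], "-")^2
  nn <- sqrt(apply(d2, 1, min))
  unname(stats::quantile(nn, 0.95, type = 7))
}

#' 95th-percentile Hausdorff distance between mask boundaries
#'
#' The larger of the two directed 95th-percentile nearest-neighbor Euclidean
#' distances between the boundary pixel sets of the predicted and reference
#' masks. Symmetric in its arguments. Returns `NA` (with a warning) when
#' either mask has no foreground, so an undefined distance is never silently
#' reported as 0.
#'
#' @param pred,truth binary (0/1) arrays of identical shape.
#' @return nonnegative pixel distance, or `NA_real_` if undefined.
#' @export
#' @examples
#' a <- matrix(0, 5, 6); a[1, 1] <- 1
#' b <- matrix(0, 5, 6); b[4, 5] <- 1
#' hd95(a, b) # 5 (Euclidean distance between the two single pixels)
hd95 <- function(pred, truth) {
  check_binary_pair(pred, truth)
  A <- boundary_points(pred)
  B <- boundary_points(truth)
  if (nrow(A) == 0L || nrow(B) == 0L) {
    warning("hd95 undefined: at least one mask has no foreground")
    return(NA_real_)
  }
  max(directed_p95(A, B), directed_p95(B, A))
}

#' Write a metric report to CSV and JSON
#'
#' @param report data frame with one row per image (as returned by
#'   [cmd_eval()]); a summary row of per-image means is appended to the CSV.
#' @param path_csv,path_json output paths; either may be `NULL` to skip.
#' @return the report, invisibly.
#' @export
write_metric_report <- function(report, path_csv = NULL, path_json = NULL) {
  if (!is.null(path_csv)) {
    out <- report
    if (nrow(report) > 0L) {
      num <- vapply(report, is.numeric, logical(1))
      summ <- report[1, , drop = FALSE]
      summ[, num] <- lapply(report[, num, drop = FALSE],
                            function(x) mean(x, na.rm = TRUE))
      summ[, !num] <- "mean"
      out <- rbind(report, summ)
    }
    utils::write.csv(out, path_csv, row.names = FALSE)
  }
  if (!is.null(path_json)) {
    jsonlite::write_json(report, path_json, dataframe = "rows",
                         auto_unbox = TRUE, digits = NA, na = "null")
  }
  invisible(report)
}
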