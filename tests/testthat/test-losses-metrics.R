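# Compound BCE + Dice loss and the evaluation metrics

test_that("BCE term is log(2) for zero logits on a half-ones mask", {
  t <- matrix(c(1, 1, 0, 0), 2)
  z <- matrix(0, 2, 2)
  # dice weight zero isolates the BCE component
  expect_equal(bce_dice_loss(z, t, w_bce = 1, w_dice = 0), log(2),
               tolerance = 1e-12)
})

test_that("loss vanishes under perfect confident prediction", {
  t <- matrix(c(1, 0, 1, 0, 0, 1), 2)
  z <- ifelse(t == 1, 50, -50)
  expect_lt(bce_dice_loss(z, t), 1e-6)
})

test_that("weighted loss equals the independently computed two-term sum", {
  set.seed(1)
  z <- matrix(rnorm(64), 8)
  t <- matrix(rbinom(64, 1, 0.3), 8)
  p <- 1 / (1 + exp(-z))
  bce <- mean(-(t * log(p) + (1 - t) * log(1 - p)))
  dice <- (2 * sum(p * t) + 1) / (sum(p) + sum(t) + 1)
  for (w in list(c(0.5, 0.5), c(0.3, 0.7), c(0.7, 0.3))) {
    expect_equal(bce_dice_loss(z, t, w[1], w[2]),
                 w[1] * bce + w[2] * (1 - dice), tolerance = 1e-10)
  }
  expect_error(bce_dice_loss(z, matrix(0.5, 8, 8)), "binary")
})

test_that("loss decreases along a convex path toward the truth", {
  set.seed(2)
  t <- matrix(rbinom(100, 1, 0.2), 10)
  z_bad <- matrix(rnorm(100, sd = 2), 10)
  z_good <- ifelse(t == 1, 8, -8)
  alphas <- seq(0, 1, length.out = 5)
  losses <- vapply(alphas, function(a) {
    bce_dice_loss((1 - a) * z_bad + a * z_good, t)
  }, numeric(1))
  expect_true(all(diff(losses) < 0))
})

test_that("confusion counts partition the pixels", {
  p <- matrix(1, 4, 4)
  expect_identical(unname(confusion_counts(p, p)), c(16L, 0L, 0L, 0L))
  t <- 1 - p
  cc <- confusion_counts(p, t)
  expect_identical(unname(cc[c("TP", "TN")]), c(0L, 0L))
  # enumerated 3x3 fixture
  pred <- matrix(c(1, 1, 0, 0, 1, 0, 0, 0, 0), 3, byrow = TRUE)
  truth <- matrix(c(1, 0, 0, 0, 1, 1, 0, 0, 0), 3, byrow = TRUE)
  expect_identical(unname(confusion_counts(pred, truth)), c(2L, 1L, 1L, 5L))
  expect_error(confusion_counts(pred, truth[1:2, ]), "identical shapes")
  expect_error(confusion_counts(pred * 0.5, truth), "binary")
})

test_that("overlap metrics match direct substitution on the 3x3 fixture", {
  pred <- matrix(c(1, 1, 0, 0, 1, 0, 0, 0, 0), 3, byrow = TRUE)
  truth <- matrix(c(1, 0, 0, 0, 1, 1, 0, 0, 0), 3, byrow = TRUE)
  m <- segmentation_metrics(pred, truth, with_hd95 = FALSE)
  expect_equal(unname(m["iou"]), 0.5)
  expect_equal(unname(m["dice"]), 2 / 3)
  expect_equal(unname(m["recall"]), 2 / 3)
  expect_equal(unname(m["precision"]), 2 / 3)
  expect_equal(unname(m["accuracy"]), 7 / 9)
})

test_that("degenerate mask conventions", {
  ones <- matrix(1, 3, 3)
  zeros <- matrix(0, 3, 3)
  m <- segmentation_metrics(ones, ones, with_hd95 = FALSE)
  expect_true(all(m == 1))
  # empty vs empty is perfect agreement
  m0 <- segmentation_metrics(zeros, zeros, with_hd95 = FALSE)
  expect_equal(unname(m0[c("iou", "dice")]), c(1, 1))
  # empty prediction against nonempty truth: zero overlap, precision 0
  m1 <- segmentation_metrics(zeros, ones, with_hd95 = FALSE)
  expect_equal(unname(m1[c("iou", "dice", "recall", "precision")]),
               c(0, 0, 0, 0))
})

test_that("Dice = 2 IoU / (1 + IoU) over randomized counts, and dice >= iou", {
  set.seed(3)
  for (i in 1:200) {
    tp <- sample(0:50, 1); fp <- sample(0:50, 1); fn <- sample(0:50, 1)
    m <- fedunetpp:::metrics_from_counts(tp, fp, fn, tn = 10)
    expect_equal(unname(m["dice"]), 2 * m[["iou"]] / (1 + m[["iou"]]),
                 tolerance = 1e-12)
    expect_gte(m[["dice"]], m[["iou"]])
  }
})

test_that("metrics are invariant under joint translation of both masks", {
  set.seed(4)
  pred <- matrix(0, 12, 12); pred[3:5, 4:6] <- 1
  truth <- matrix(0, 12, 12); truth[4:6, 4:7] <- 1
  m1 <- segmentation_metrics(pred, truth)
  shift <- function(m, dr, dc) {
    out <- matrix(0, nrow(m), ncol(m))
    out[(1 + dr):nrow(m), (1 + dc):ncol(m)] <-
      m[1:(nrow(m) - dr), 1:(ncol(m) - dc)]
    out
  }
  m2 <- segmentation_metrics(shift(pred, 3, 2), shift(truth, 3, 2))
  expect_equal(m1[c("iou", "dice", "recall", "precision", "hd95")],
               m2[c("iou", "dice", "recall", "precision", "hd95")],
               tolerance = 1e-12)
})

test_that("hd95: identity, singleton pixels, symmetry, undefined case", {
  m <- matrix(0, 8, 8); m[3:5, 3:4] <- 1
  expect_equal(hd95(m, m), 0)
  a <- matrix(0, 5, 6); a[1, 1] <- 1
  b <- matrix(0, 5, 6); b[4, 5] <- 1
  expect_equal(hd95(a, b), 5) # 3-4-5 triangle
  expect_equal(hd95(b, a), hd95(a, b))
  expect_warning(h <- hd95(matrix(0, 4, 4), m[1:4, 1:4]), "undefined")
  expect_true(is.na(h))
})

test_that("hd95 equals the brute-force all-pairs oracle on random masks", {
  set.seed(5)
  for (rep in 1:10) {
    a <- matrix(rbinom(15 * 15, 1, 0.12), 15)
    b <- matrix(rbinom(15 * 15, 1, 0.12), 15)
    A <- fedunetpp:::boundary_points(a)
    B <- fedunetpp:::boundary_points(b)
    if (nrow(A) == 0 || nrow(B) == 0) next
    expect_lte(nrow(A), 50)
    expect_equal(hd95(a, b), naive_hd95_points(A, B), tolerance = 1e-12)
    expect_equal(hd95(a, b), hd95(b, a), tolerance = 1e-12)
  }
})

test_that("boundary extraction uses 4-connectivity", {
  # a filled 4x4 square: interior 2x2 pixels have no background 4-neighbor
  m <- matrix(0, 8, 8); m[3:6, 3:6] <- 1
  bp <- fedunetpp:::boundary_points(m)
  expect_identical(nrow(bp), 12L) # 16 foreground - 4 interior
  expect_false(any(bp[, 1] %in% 4:5 & bp[, 2] %in% 4:5))
})
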