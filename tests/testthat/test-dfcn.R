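# Dynamic frequency context network: expansion/split, gated local path,
# multi-scale patch FFT filtering

test_that("expansion/split produces two equal-shape C-channel maps", {
  set.seed(1)
  dfc <- dfcn_module(8)
  x <- rand_bchw(1, 8, 16, 16)
  xv <- fedunetpp:::vr(fedunetpp:::as_internal(x))
  ctx <- list(tape = NULL, training = FALSE)
  xe <- fedunetpp:::mod_fwd(dfc$children$expand, xv, ctx)
  expect_identical(dim(xe$v), c(16L, 16L, 16L, 1L))
  sp <- fedunetpp:::op_split(NULL, xe, c(8L, 8L))
  expect_identical(dim(sp[[1]]$v), dim(sp[[2]]$v))

  # identity-initialized expansion (stacked identity, zero bias): X1 = X2 = x
  dfc$children$expand$params$W$v <- cbind(diag(8), diag(8))
  dfc$children$expand$params$b$v[] <- 0
  xe2 <- fedunetpp:::mod_fwd(dfc$children$expand, xv, ctx)
  sp2 <- fedunetpp:::op_split(NULL, xe2, c(8L, 8L))
  expect_equal(sp2[[1]]$v, xv$v, tolerance = 1e-12)
  expect_equal(sp2[[2]]$v, xv$v, tolerance = 1e-12)

  # parameter count of the expansion conv at C = 64: 64*128 + 128
  expect_identical(
    count_trainable_params(dfcn_module(64)$children$expand), 64 * 128 + 128)
})

test_that("gated local path: multiplicative gate and depthwise oracle", {
  set.seed(2)
  dfc <- dfcn_module(3)
  ctx <- list(tape = NULL, training = FALSE)
  x1 <- fedunetpp:::vr(array(rnorm(5 * 5 * 3), c(5, 5, 3, 1)))
  x2z <- fedunetpp:::vr(array(0, c(5, 5, 3, 1)))
  # x2 = 0 annihilates the output (zero the dw2 bias so its output is 0)
  dfc$children$dw2$params$b$v[] <- 0
  d1 <- fedunetpp:::mod_fwd(dfc$children$dw1, x1, ctx)
  d2 <- fedunetpp:::mod_fwd(dfc$children$dw2, x2z, ctx)
  out <- fedunetpp:::op_mul(NULL, fedunetpp:::op_gelu(NULL, d1), d2)
  expect_true(all(out$v == 0))
  expect_identical(dim(out$v), c(5L, 5L, 3L, 1L))

  # gate forced to 1: output equals the depthwise convolution of x2,
  # checked against a direct per-channel convolution oracle on a 5x5 input
  w <- matrix(rnorm(9 * 3), 9, 3)
  b <- rnorm(3)
  dw <- fedunetpp:::layer_dwconv(3)
  dw$params$W$v <- w
  dw$params$b$v <- b
  x2 <- array(rnorm(5 * 5 * 3), c(5, 5, 3, 1))
  got <- fedunetpp:::mod_fwd(dw, fedunetpp:::vr(x2), ctx)$v
  for (c in 1:3) {
    wc <- array(0, c(3, 3, 1, 1))
    wc[, , 1, 1] <- matrix(w[, c], 3, 3) # idx = i + (j-1)*3 layout
    yo <- naive_conv2d(array(x2[, , c, 1], c(5, 5, 1)), wc, b[c])
    expect_equal(got[, , c, 1], yo[, , 1], tolerance = 1e-10)
  }
})

test_that("unit weights give the identity filter at every scale", {
  set.seed(3)
  x <- rand_bchw(1, 4, 64, 64)
  for (P in c(4, 8, 16)) {
    y <- freq_filter_scale(x, P)
    expect_lt(max(abs(y - x)), 1e-5)
  }
})

test_that("DC-only weights replace every tile by its mean", {
  set.seed(4)
  x <- rand_bchw(1, 2, 8, 8)
  P <- 4
  w <- array(0, c(2, P, P / 2 + 1))
  w[, 1, 1] <- 1 # DC bin only
  y <- freq_filter_scale(x, P, w)
  for (c in 1:2) {
    for (th in 1:2) {
      for (tw in 1:2) {
        rows <- (th - 1) * P + 1:P
        cols <- (tw - 1) * P + 1:P
        tile <- x[1, c, rows, cols]
        expect_equal(y[1, c, rows, cols],
                     array(mean(tile), c(P, P)), tolerance = 1e-10)
      }
    }
  }
})

test_that("filter is linear and respects uniform scaling", {
  set.seed(5)
  x <- rand_bchw(1, 3, 12, 12)
  y <- rand_bchw(1, 3, 12, 12)
  w <- array(runif(3 * 4 * 3, 0.5, 1.5), c(3, 4, 3))
  f <- function(z) freq_filter_scale(z, 4, w)
  expect_equal(f(2.5 * x - 1.5 * y), 2.5 * f(x) - 1.5 * f(y),
               tolerance = 1e-9)
  # w = 2 doubles the input
  expect_equal(freq_filter_scale(x, 4, array(2, c(3, 4, 3))), 2 * x,
               tolerance = 1e-9)
})

test_that("Parseval scaling holds on 8x8 tiles against a direct DFT oracle", {
  set.seed(6)
  P <- 8
  x <- array(rnorm(P * P), c(1, 1, P, P))
  wh <- array(runif(P * (P / 2 + 1), 0.2, 2), c(1, P, P / 2 + 1))
  # a real amplitude filter must weight conjugate bin pairs equally; within
  # the DC and Nyquist columns that means w[a] = w[P - a]
  for (cl in c(1, P / 2 + 1)) {
    for (a in (P / 2 + 2):P) wh[1, a, cl] <- wh[1, P - a + 2, cl]
  }
  y <- freq_filter_scale(x, P, wh)
  # spectral energy computed with the explicit-sum DFT and the mirrored
  # full-grid weights: ||y||^2 = (1/P^2) * sum |X_k W_k|^2
  Xh <- naive_dft2(x[1, 1, , ])
  wfull <- matrix(0, P, P)
  for (a in 1:P) {
    for (b in 1:P) {
      if (b - 1 <= P / 2) {
        wfull[a, b] <- wh[1, a, b]
      } else {
        wfull[a, b] <- wh[1, ((P - (a - 1)) %% P) + 1, P - (b - 1) + 1]
      }
    }
  }
  expect_equal(sum(y^2), sum(Mod(Xh * wfull)^2) / P^2, tolerance = 1e-8)
  # and the filter itself agrees with the oracle transform chain
  yo <- Re(fft(fft(x[1, 1, , ]) * wfull, inverse = TRUE)) / P^2
  expect_equal(y[1, 1, , ], yo, tolerance = 1e-8)
})

test_that("non-divisible maps are reflect-padded and cropped correctly", {
  set.seed(7)
  dfc <- dfcn_module(2)
  x <- rand_bchw(1, 2, 100, 100)
  y <- module_forward(dfc, x, training = TRUE)
  expect_identical(dim(y), c(1L, 2L, 100L, 100L))
  expect_true(all(is.finite(y)))
  # the padded-region-free interior of a padded computation matches the
  # divisible-size result: at P = 8 a 100x100 map is reflect-padded to 104,
  # but tiles fully inside 1:96 are unaffected, so they must equal the tiles
  # of the unpadded 96x96 computation
  w <- array(runif(2 * 8 * 5, 0.5, 1.5), c(2, 8, 5))
  full <- freq_filter_scale(x, 8, w)
  sub <- freq_filter_scale(x[, , 1:96, 1:96, drop = FALSE], 8, w)
  expect_equal(full[, , 1:96, 1:96], sub[, , , ], tolerance = 1e-10)
})

test_that("dfcn with unit weights and averaging projection is purely local", {
  set.seed(8)
  dfc <- dfcn_module(3)
  # projection averaging the three identical filtered copies
  dfc$children$proj$params$W$v <- rbind(diag(3), diag(3), diag(3)) / 3
  dfc$children$proj$params$b$v[] <- 0
  x <- rand_bchw(2, 3, 32, 32)
  y <- module_forward(dfc, x)
  xv <- fedunetpp:::vr(fedunetpp:::as_internal(x))
  xl <- fedunetpp:::dfcn_local(dfc, xv, list(tape = NULL, training = FALSE))
  expect_equal(y, fedunetpp:::as_external(xl$v), tolerance = 1e-6)
})

test_that("dfcn is a drop-in shape-preserving module", {
  set.seed(9)
  dfc <- dfcn_module(32)
  x <- rand_bchw(2, 32, 64, 64)
  expect_identical(dim(module_forward(dfc, x)), dim(x))
})
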