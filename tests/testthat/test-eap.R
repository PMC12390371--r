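# Efficient attention pyramid: ASPP branches and the directional gate

test_that("aspp concatenates five branches to 5C channels", {
  set.seed(2)
  eap <- eap_module(8, reduction = 4)
  x <- rand_bchw(1, 8, 16, 16)
  fcat <- module_forward(eap$children$aspp, x, training = TRUE)
  expect_identical(dim(fcat), c(1L, 40L, 16L, 16L))
  # full module is a C -> C drop-in
  y <- module_forward(eap, x, training = TRUE)
  expect_identical(dim(y), c(1L, 8L, 16L, 16L))
})

test_that("pooling branch equals the constant on constant input", {
  eap <- eap_module(4, reduction = 4)
  x <- array(2.5, c(1, 4, 8, 8))
  xv <- fedunetpp:::vr(fedunetpp:::as_internal(x))
  gp <- fedunetpp:::op_gap(NULL, xv)
  expect_equal(as.vector(gp$v), rep(2.5, 4))
})

test_that("dilated branch support matches the dilated stencil offsets", {
  # impulse in the middle of a 13x13 single-channel image through the
  # dilation-6 branch: nonzero output only at offsets {-6, 0, +6} per axis
  br <- fedunetpp:::aspp_branch(1, k = 3, dilation = 6)
  conv <- br$children$conv
  conv$params$W$v[] <- 1
  conv$params$b$v[] <- 0
  x <- array(0, c(1, 1, 13, 13))
  x[1, 1, 7, 7] <- 1
  y <- module_forward(conv, x)
  nz <- which(abs(y[1, 1, , ]) > 1e-12, arr.ind = TRUE)
  expect_setequal(nz[, 1], c(1, 7, 13))
  expect_setequal(nz[, 2], c(1, 7, 13))
  expect_identical(nrow(nz), 9L)
  # and the same impulse against the direct convolution oracle
  w <- array(rnorm(9), c(3, 3, 1, 1))
  conv$params$W$v <- pack_kernel(w)
  y2 <- module_forward(conv, x)
  yo <- naive_conv2d(array(x[1, 1, , ], c(13, 13, 1)), w, dilation = 6)
  expect_equal(array(y2[1, 1, , ], c(13, 13)), yo[, , 1], tolerance = 1e-10)
})

test_that("dilation-1 branch equals a plain 3x3 convolution oracle on 8x8", {
  set.seed(9)
  w <- array(rnorm(9 * 2 * 2), c(3, 3, 2, 2))
  b <- rnorm(2)
  lc <- fedunetpp:::layer_conv(2, 2, k = 3, dilation = 1)
  lc$params$W$v <- pack_kernel(w)
  lc$params$b$v <- b
  x <- rand_bchw(1, 2, 8, 8)
  y <- module_forward(lc, x)
  yo <- naive_conv2d(aperm(x[1, , , ], c(2, 3, 1)), w, b)
  expect_equal(aperm(y[1, , , ], c(2, 3, 1)), yo, tolerance = 1e-10)
})

test_that("attention map lies strictly in (0,1) and bounds the output", {
  set.seed(4)
  eap <- eap_module(8, reduction = 4)
  x <- rand_bchw(2, 8, 12, 12)
  xv <- fedunetpp:::vr(fedunetpp:::as_internal(x))
  ctx <- list(tape = NULL, training = TRUE)
  fcat <- fedunetpp:::mod_fwd(eap$children$aspp, xv, ctx)
  y <- fedunetpp:::mod_fwd(eap$children$ema, fcat, ctx)
  # recompute Fr to check |y| <= 2 |Fr| elementwise
  ema <- eap$children$ema
  fr <- fedunetpp:::op_elu(NULL, fedunetpp:::mod_fwd(
    ema$children$bn_r, fedunetpp:::mod_fwd(ema$children$conv_r, fcat, ctx),
    ctx))
  expect_true(all(abs(y$v) <= 2 * abs(fr$v) + 1e-12))
})

test_that("gate limits: A -> 0 gives Fr, A = 1 doubles Fr", {
  set.seed(6)
  eap <- eap_module(4, reduction = 4)
  ema <- eap$children$ema
  x <- rand_bchw(1, 4, 6, 6)
  xv <- fedunetpp:::vr(fedunetpp:::as_internal(x))
  ctx <- list(tape = NULL, training = TRUE)
  fcat <- fedunetpp:::mod_fwd(eap$children$aspp, xv, ctx)
  fr <- fedunetpp:::op_elu(NULL, fedunetpp:::mod_fwd(
    ema$children$bn_r, fedunetpp:::mod_fwd(ema$children$conv_r, fcat, ctx),
    ctx))
  # drive both gate logits to -inf / +inf via the gate conv biases
  for (sgn in c(-1, 1)) {
    ema$children$conv_h$params$W$v[] <- 0
    ema$children$conv_w$params$W$v[] <- 0
    ema$children$conv_h$params$b$v[] <- sgn * 50
    ema$children$conv_w$params$b$v[] <- sgn * 50
    y <- fedunetpp:::mod_fwd(ema, fcat, ctx)
    expected <- if (sgn < 0) fr$v else 2 * fr$v
    expect_equal(y$v, expected, tolerance = 1e-8)
  }
})

test_that("output is equivariant under batch permutation", {
  set.seed(7)
  eap <- eap_module(4, reduction = 4)
  x <- rand_bchw(3, 4, 8, 8)
  y <- module_forward(eap, x)
  perm <- c(3, 1, 2)
  y2 <- module_forward(eap, x[perm, , , , drop = FALSE])
  expect_equal(y2, y[perm, , , , drop = FALSE], tolerance = 1e-10)
})

test_that("zero input produces finite output", {
  eap <- eap_module(4, reduction = 4)
  y <- module_forward(eap, array(0, c(1, 4, 8, 8)), training = TRUE)
  expect_true(all(is.finite(y)))
})

test_that("non-finite input and bad reduction are rejected", {
  eap <- eap_module(4, reduction = 4)
  x <- array(0, c(1, 4, 8, 8))
  x[1, 1, 1, 1] <- NaN
  expect_error(module_forward(eap, x), "non-finite")
  expect_error(eap_module(6, reduction = 4), "config error")
})

test_that("EAP parameter overhead at C = 512 matches the published delta", {
  # consistency check: the full-network parameter delta attributable to the
  # attention pyramid is approximately 8.96 M (within 0.2 M)
  added <- count_trainable_params(eap_module(512))
  expect_lt(abs(added / 1e6 - 8.96), 0.2)
})
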