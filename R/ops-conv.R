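# Convolution, normalization, pooling and resampling ops on (H, W, C, B)
# arrays. Convolutions use im2col + BLAS matrix multiplication; backward
# passes are the standard transposed forms (col2im scatter-add for the input
# gradient). All convolutions are stride-1 "same" convolutions.

# im2col: padded input -> (H*W, k*k*C, B) patch tensor
im2col <- function(v, k, dilation) {
  dm <- dim(v)
  H <- dm[1]; W <- dm[2]; C <- dm[3]; B <- dm[4]
  npos <- H * W
  k2 <- k * k
  p <- as.integer(dilation * (k - 1L) / 2L)
  Hp <- H + 2L * p; Wp <- W + 2L * p
  xp <- array(0, c(Hp, Wp, C, B))
  xp[(p + 1L):(p + H), (p + 1L):(p + W), , ] <- v
  P <- array(0, c(npos, k2 * C, B))
  idx <- 0L
  for (j in seq_len(k)) {
    for (i in seq_len(k)) {
      idx <- idx + 1L
      sl <- xp[seq_len(H) + (i - 1L) * dilation,
               seq_len(W) + (j - 1L) * dilation, , , drop = FALSE]
      dim(sl) <- c(npos, C, B)
      P[, ((idx - 1L) * C + 1L):(idx * C), ] <- sl
    }
  }
  P
}

# col2im: scatter-add patch gradients back to the (padded, then cropped) input
col2im <- function(gP, k, dilation, H, W, C, B) {
  p <- as.integer(dilation * (k - 1L) / 2L)
  Hp <- H + 2L * p; Wp <- W + 2L * p
  gpad <- array(0, c(Hp, Wp, C, B))
  npos <- H * W
  idx <- 0L
  for (j in seq_len(k)) {
    for (i in seq_len(k)) {
      idx <- idx + 1L
      rows <- seq_len(H) + (i - 1L) * dilation
      cols <- seq_len(W) + (j - 1L) * dilation
      sl <- gP[, ((idx - 1L) * C + 1L):(idx * C), , drop = FALSE]
      dim(sl) <- c(H, W, C, B)
      gpad[rows, cols, , ] <- gpad[rows, cols, , , drop = FALSE] + sl
    }
  }
  gpad[(p + 1L):(p + H), (p + 1L):(p + W), , , drop = FALSE]
}

# x: variable (H, W, C, B); W: variable, matrix (k*k*Cin, Cout); b: variable
# vector (Cout) or NULL
op_conv2d <- function(tape, x, W, b, k, dilation = 1L) {
  v <- x$v
  dm <- dim(v)
  H <- dm[1]; Wd <- dm[2]; C <- dm[3]; B <- dm[4]
  Wm <- W$v
  k2 <- k * k
  if (nrow(Wm) != k2 * C) {
    stop("input-contract error: expected ", nrow(Wm) / k2,
         " input channels, got ", C)
  }
  cout <- ncol(Wm)
  npos <- H * Wd
  if (k == 1L) {
    P <- v
    dim(P) <- c(npos, C, B)
  } else {
    P <- im2col(v, k, dilation)
  }
  bv <- if (!is.null(b)) b$v else NULL
  out <- array(0, c(H, Wd, cout, B))
  dim(out) <- c(npos, cout, B)
  for (bb in seq_len(B)) {
    Y <- matrix(P[, , bb], npos, k2 * C) %*% Wm
    if (!is.null(bv)) Y <- Y + rep(bv, each = npos)
    out[, , bb] <- Y
  }
  dim(out) <- c(H, Wd, cout, B)
  xneeds <- needs_grad(x)
  make_node(tape, out, function(g) {
    dim(g) <- c(npos, cout, B)
    gW <- matrix(0, k2 * C, cout)
    gb <- if (!is.null(b)) numeric(cout) else NULL
    gP <- if (xneeds) array(0, c(npos, k2 * C, B)) else NULL
    tWm <- t(Wm)
    for (bb in seq_len(B)) {
      Gb <- matrix(g[, , bb], npos, cout)
      Pb <- matrix(P[, , bb], npos, k2 * C)
      gW <- gW + crossprod(Pb, Gb)
      if (!is.null(gb)) gb <- gb + colSums(Gb)
      if (xneeds) gP[, , bb] <- Gb %*% tWm
    }
    acc_grad(W, gW)
    if (!is.null(b)) acc_grad(b, gb)
    if (xneeds) {
      if (k == 1L) {
        dim(gP) <- c(H, Wd, C, B)
        acc_grad(x, gP)
      } else {
        acc_grad(x, col2im(gP, k, dilation, H, Wd, C, B))
      }
    }
  })
}

# depthwise 3x3 (one k x k filter per channel); W: variable (k*k, C)
op_dwconv2d <- function(tape, x, W, b, k = 3L) {
  v <- x$v
  dm <- dim(v)
  H <- dm[1]; Wd <- dm[2]; C <- dm[3]; B <- dm[4]
  npos <- H * Wd
  p <- as.integer((k - 1L) / 2L)
  Hp <- H + 2L * p; Wp <- Wd + 2L * p
  xp <- array(0, c(Hp, Wp, C, B))
  xp[(p + 1L):(p + H), (p + 1L):(p + Wd), , ] <- v
  Wm <- W$v
  out <- array(0, c(H, Wd, C, B))
  idx <- 0L
  for (j in seq_len(k)) {
    for (i in seq_len(k)) {
      idx <- idx + 1L
      sl <- xp[seq_len(H) + (i - 1L), seq_len(Wd) + (j - 1L), , , drop = FALSE]
      out <- out + as.vector(sl) * bc_ch(Wm[idx, ], npos, B)
    }
  }
  if (!is.null(b)) out <- out + bc_ch(b$v, npos, B)
  dim(out) <- c(H, Wd, C, B)
  xneeds <- needs_grad(x)
  make_node(tape, out, function(g) {
    gW <- matrix(0, k * k, C)
    gpad <- if (xneeds) array(0, c(Hp, Wp, C, B)) else NULL
    idx <- 0L
    for (j in seq_len(k)) {
      for (i in seq_len(k)) {
        idx <- idx + 1L
        rows <- seq_len(H) + (i - 1L)
        cols <- seq_len(Wd) + (j - 1L)
        sl <- xp[rows, cols, , , drop = FALSE]
        gW[idx, ] <- ch_sum(as.vector(g) * as.vector(sl), npos, C, B)
        if (xneeds) {
          gsl <- as.vector(g) * bc_ch(Wm[idx, ], npos, B)
          dim(gsl) <- c(H, Wd, C, B)
          gpad[rows, cols, , ] <- gpad[rows, cols, , , drop = FALSE] + gsl
        }
      }
    }
    acc_grad(W, gW)
    if (!is.null(b)) acc_grad(b, ch_sum(g, npos, C, B))
    if (xneeds) {
      acc_grad(x, gpad[(p + 1L):(p + H), (p + 1L):(p + Wd), , , drop = FALSE])
    }
  })
}

# Batch normalization over (H, W, B) per channel. `layer` is the module
# environment carrying gamma/beta parameters and running-statistic buffers.
op_bn <- function(tape, x, layer, training) {
  v <- x$v
  dm <- dim(v)
  H <- dm[1]; W <- dm[2]; C <- dm[3]; B <- dm[4]
  npos <- H * W
  N <- npos * B
  gamma <- layer$params$gamma
  beta <- layer$params$beta
  eps <- layer$eps
  if (training) {
    m <- ch_sum(v, npos, C, B) / N
    xc <- v - bc_ch(m, npos, B)
    va <- ch_sum(xc * xc, npos, C, B) / N
    sig <- sqrt(va + eps)
    xhat <- xc * bc_ch(1 / sig, npos, B)
    dim(xhat) <- dm
    # running stats: unbiased variance, as is conventional
    mom <- layer$momentum
    ub <- if (N > 1L) va * N / (N - 1L) else va
    layer$buffers$running_mean <- (1 - mom) * layer$buffers$running_mean + mom * m
    layer$buffers$running_var <- (1 - mom) * layer$buffers$running_var + mom * ub
    y <- xhat * bc_ch(gamma$v, npos, B) + bc_ch(beta$v, npos, B)
    dim(y) <- dm
    xneeds <- needs_grad(x)
    make_node(tape, y, function(g) {
      gv <- as.vector(g)
      acc_grad(gamma, ch_sum(gv * as.vector(xhat), npos, C, B))
      acc_grad(beta, ch_sum(gv, npos, C, B))
      if (xneeds) {
        mg <- ch_sum(gv, npos, C, B) / N
        mgx <- ch_sum(gv * as.vector(xhat), npos, C, B) / N
        dx <- bc_ch(gamma$v / sig, npos, B) *
          (gv - bc_ch(mg, npos, B) - as.vector(xhat) * bc_ch(mgx, npos, B))
        dim(dx) <- dm
        acc_grad(x, dx)
      }
    })
  } else {
    sig <- sqrt(layer$buffers$running_var + eps)
    y <- (as.vector(v) - bc_ch(layer$buffers$running_mean, npos, B)) *
      bc_ch(gamma$v / sig, npos, B) + bc_ch(beta$v, npos, B)
    dim(y) <- dm
    xneeds <- needs_grad(x)
    make_node(tape, y, function(g) {
      gv <- as.vector(g)
      xhat_e <- (as.vector(v) - bc_ch(layer$buffers$running_mean, npos, B)) *
        bc_ch(1 / sig, npos, B)
      acc_grad(gamma, ch_sum(gv * xhat_e, npos, C, B))
      acc_grad(beta, ch_sum(gv, npos, C, B))
      if (xneeds) {
        dx <- gv * bc_ch(gamma$v / sig, npos, B)
        dim(dx) <- dm
        acc_grad(x, dx)
      }
    })
  }
}

# 2x2 max pooling, stride 2 (H, W must be even)
op_maxpool2 <- function(tape, x) {
  v <- x$v
  dm <- dim(v)
  H <- dm[1]; W <- dm[2]; C <- dm[3]; B <- dm[4]
  if (H %% 2L != 0L || W %% 2L != 0L) {
    stop("max pooling requires even spatial dimensions, got ", H, "x", W)
  }
  H2 <- H %/% 2L; W2 <- W %/% 2L
  xr <- v
  dim(xr) <- c(2L, H2, 2L, W2, C, B)
  a11 <- xr[1L, , 1L, , , , drop = TRUE]
  a21 <- xr[2L, , 1L, , , , drop = TRUE]
  a12 <- xr[1L, , 2L, , , , drop = TRUE]
  a22 <- xr[2L, , 2L, , , , drop = TRUE]
  dms <- c(H2, W2, C, B)
  dim(a11) <- dms; dim(a21) <- dms; dim(a12) <- dms; dim(a22) <- dms
  m <- pmax(a11, a21, a12, a22)
  dim(m) <- dms
  make_node(tape, m, function(g) {
    # ties routed to the first maximal position (fixed order)
    m1 <- a11 == m
    m2 <- (a21 == m) & !m1
    m3 <- (a12 == m) & !(m1 | m2)
    m4 <- (a22 == m) & !(m1 | m2 | m3)
    gr <- array(0, c(2L, H2, 2L, W2, C, B))
    gr[1L, , 1L, , , ] <- g * m1
    gr[2L, , 1L, , , ] <- g * m2
    gr[1L, , 2L, , , ] <- g * m3
    gr[2L, , 2L, , , ] <- g * m4
    dim(gr) <- c(H, W, C, B)
    acc_grad(x, gr)
  })
}

# 1D linear-interpolation matrix (half-pixel-center convention)
interp_mat <- function(n_out, n_in) {
  M <- matrix(0, n_out, n_in)
  for (o in seq_len(n_out)) {
    s <- (o - 0.5) * n_in / n_out - 0.5
    s <- min(max(s, 0), n_in - 1)
    i0 <- as.integer(floor(s))
    w1 <- s - i0
    i1 <- min(i0 + 1L, n_in - 1L)
    M[o, i0 + 1L] <- M[o, i0 + 1L] + (1 - w1)
    M[o, i1 + 1L] <- M[o, i1 + 1L] + w1
  }
  M
}

# separable bilinear resize by matrices Rh (Ho x H), Rw (Wo x W)
resize_apply <- function(v, Rh, Rw) {
  dm <- dim(v)
  H <- dm[1]; W <- dm[2]; C <- dm[3]; B <- dm[4]
  Ho <- nrow(Rh); Wo <- nrow(Rw)
  y1 <- Rh %*% matrix(v, H)
  dim(y1) <- c(Ho, W, C, B)
  y1 <- aperm(y1, c(2L, 1L, 3L, 4L))
  y2 <- Rw %*% matrix(y1, W)
  dim(y2) <- c(Wo, Ho, C, B)
  aperm(y2, c(2L, 1L, 3L, 4L))
}

# 2x bilinear upsampling
op_upsample2 <- function(tape, x) {
  v <- x$v
  dm <- dim(v)
  H <- dm[1]; W <- dm[2]
  Rh <- interp_mat(2L * H, H)
  Rw <- interp_mat(2L * W, W)
  y <- resize_apply(v, Rh, Rw)
  make_node(tape, y, function(g) {
    acc_grad(x, resize_apply(g, t(Rh), t(Rw)))
  })
}

## ---- reductions and broadcasts for attention paths -------------------------

# global average pool -> (1, 1, C, B)
op_gap <- function(tape, x) {
  v <- x$v
  dm <- dim(v)
  npos <- dm[1] * dm[2]
  y <- colMeans(matrix(v, npos))
  dim(y) <- c(1L, 1L, dm[3], dm[4])
  make_node(tape, y, function(g) {
    gx <- rep(as.vector(g), each = npos) / npos
    dim(gx) <- dm
    acc_grad(x, gx)
  })
}

# mean over width -> (H, 1, C, B)
op_mean_w <- function(tape, x) {
  v <- x$v
  dm <- dim(v)
  H <- dm[1]; W <- dm[2]; C <- dm[3]; B <- dm[4]
  a <- aperm(v, c(1L, 3L, 4L, 2L)) # (H, C, B, W)
  y <- rowSums(a, dims = 3L) / W
  dim(y) <- c(H, 1L, C, B)
  make_node(tape, y, function(g) {
    gx <- g[, rep(1L, W), , , drop = FALSE] / W
    dim(gx) <- dm
    acc_grad(x, gx)
  })
}

# mean over height -> (1, W, C, B)
op_mean_h <- function(tape, x) {
  v <- x$v
  dm <- dim(v)
  H <- dm[1]; W <- dm[2]; C <- dm[3]; B <- dm[4]
  y <- colSums(matrix(v, H)) / H # length W*C*B
  dim(y) <- c(1L, W, C, B)
  make_node(tape, y, function(g) {
    gx <- rep(as.vector(g), each = H) / H
    dim(gx) <- dm
    acc_grad(x, gx)
  })
}

# broadcast (H, 1, C, B) across width W
op_expand_w <- function(tape, x, W) {
  v <- x$v
  dm <- dim(v)
  H <- dm[1]; C <- dm[3]; B <- dm[4]
  y <- v[, rep(1L, W), , , drop = FALSE]
  make_node(tape, y, function(g) {
    gs <- rowSums(aperm(g, c(1L, 3L, 4L, 2L)), dims = 3L)
    dim(gs) <- c(H, 1L, C, B)
    acc_grad(x, gs)
  })
}

# broadcast (1, W, C, B) across height H
op_expand_h <- function(tape, x, H) {
  v <- x$v
  dm <- dim(v)
  W <- dm[2]; C <- dm[3]; B <- dm[4]
  y <- v[rep(1L, H), , , , drop = FALSE]
  make_node(tape, y, function(g) {
    gs <- colSums(matrix(g, H))
    dim(gs) <- c(1L, W, C, B)
    acc_grad(x, gs)
  })
}

# broadcast (1, 1, C, B) across H x W
op_expand_hw <- function(tape, x, H, W) {
  v <- x$v
  dm <- dim(v)
  C <- dm[3]; B <- dm[4]
  npos <- H * W
  y <- rep(as.vector(v), each = npos)
  dim(y) <- c(H, W, C, B)
  make_node(tape, y, function(g) {
    gs <- colSums(matrix(g, npos))
    dim(gs) <- c(1L, 1L, C, B)
    acc_grad(x, gs)
  })
}

# swap H and W axes
op_transpose_hw <- function(tape, x) {
  y <- aperm(x$v, c(2L, 1L, 3L, 4L))
  make_node(tape, y, function(g) {
    acc_grad(x, aperm(g, c(2L, 1L, 3L, 4L)))
  })
}

## ---- concatenation / splitting ---------------------------------------------

# concatenate along a given axis (3 = channels, 1 = height)
op_concat <- function(tape, xs, axis = 3L) {
  dims <- lapply(xs, function(v) dim(v$v))
  sizes <- vapply(dims, function(d) d[axis], numeric(1))
  total <- sum(sizes)
  dout <- dims[[1]]
  dout[axis] <- total
  out <- array(0, dout)
  ofs <- 0L
  for (i in seq_along(xs)) {
    idx <- ofs + seq_len(sizes[i])
    if (axis == 3L) out[, , idx, ] <- xs[[i]]$v
    else if (axis == 1L) out[idx, , , ] <- xs[[i]]$v
    else stop("unsupported concat axis")
    ofs <- ofs + sizes[i]
  }
  make_node(tape, out, function(g) {
    ofs <- 0L
    for (i in seq_along(xs)) {
      idx <- ofs + seq_len(sizes[i])
      gi <- if (axis == 3L) g[, , idx, , drop = FALSE]
            else g[idx, , , , drop = FALSE]
      acc_grad(xs[[i]], gi)
      ofs <- ofs + sizes[i]
    }
  })
}

# split along a given axis into chunks of the given sizes; returns a list
op_split <- function(tape, x, sizes, axis = 3L) {
  dm <- dim(x$v)
  ofs <- 0L
  outs <- vector("list", length(sizes))
  for (i in seq_along(sizes)) {
    idx <- ofs + seq_len(sizes[i])
    vi <- if (axis == 3L) x$v[, , idx, , drop = FALSE]
          else x$v[idx, , , , drop = FALSE]
    local({
      idx_l <- idx
      outs[[i]] <<- make_node(tape, vi, function(g) {
        gz <- array(0, dm)
        if (axis == 3L) gz[, , idx_l, ] <- g else gz[idx_l, , , ] <- g
        acc_grad(x, gz)
      })
    })
    ofs <- ofs + sizes[i]
  }
  outs
}
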