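# Independent oracles used by the tests: direct (loop-based) convolution,
# explicit-sum 2D DFT, and a hand-rolled linear-interpolation percentile.
# These deliberately share no code with the implementation.

# direct 2D convolution, "same" zero padding, arbitrary dilation
# x: (H, W, Cin); w: (k, k, Cin, Cout); bias: numeric(Cout)
naive_conv2d <- function(x, w, bias = NULL, dilation = 1) {
  H <- dim(x)[1]; W <- dim(x)[2]; Cin <- dim(x)[3]
  k <- dim(w)[1]; Cout <- dim(w)[4]
  if (is.null(bias)) bias <- numeric(Cout)
  out <- array(0, c(H, W, Cout))
  ctr <- (k + 1) / 2
  for (co in seq_len(Cout)) {
    for (h in seq_len(H)) {
      for (wd in seq_len(W)) {
        s <- bias[co]
        for (ci in seq_len(Cin)) {
          for (i in seq_len(k)) {
            for (j in seq_len(k)) {
              hh <- h + (i - ctr) * dilation
              ww <- wd + (j - ctr) * dilation
              if (hh >= 1 && hh <= H && ww >= 1 && ww <= W) {
                s <- s + x[hh, ww, ci] * w[i, j, ci, co]
              }
            }
          }
        }
        out[h, wd, co] <- s
      }
    }
  }
  out
}

# pack a (k, k, Cin, Cout) kernel into the package's (k*k*Cin, Cout) layout
# (offset index idx = i + (j - 1) * k varies over blocks of Cin rows)
pack_kernel <- function(w) {
  k <- dim(w)[1]; Cin <- dim(w)[3]; Cout <- dim(w)[4]
  Wm <- matrix(0, k * k * Cin, Cout)
  for (j in seq_len(k)) {
    for (i in seq_len(k)) {
      idx <- i + (j - 1L) * k
      Wm[(idx - 1L) * Cin + seq_len(Cin), ] <- w[i, j, , ]
    }
  }
  Wm
}

# explicit-sum unnormalized 2D DFT of a P x P real matrix
naive_dft2 <- function(x) {
  P <- nrow(x)
  out <- matrix(0 + 0i, P, P)
  for (u in 0:(P - 1)) {
    for (v in 0:(P - 1)) {
      s <- 0 + 0i
      for (a in 0:(P - 1)) {
        for (b in 0:(P - 1)) {
          s <- s + x[a + 1, b + 1] * exp(-2i * pi * (u * a + v * b) / P)
        }
      }
      out[u + 1, v + 1] <- s
    }
  }
  out
}

# linear-interpolation percentile between order statistics
naive_p95 <- function(d) {
  d <- sort(d)
  n <- length(d)
  if (n == 1L) return(d)
  h <- (n - 1) * 0.95 + 1
  lo <- floor(h)
  if (lo >= n) return(d[n])
  d[lo] + (h - lo) * (d[lo + 1] - d[lo])
}

# brute-force HD95 between two point sets (all-pairs distances)
naive_hd95_points <- function(A, B) {
  dmat <- matrix(0, nrow(A), nrow(B))
  for (i in seq_len(nrow(A))) {
    for (j in seq_len(nrow(B))) {
      dmat[i, j] <- sqrt(sum((A[i, ] - B[j, ])^2))
    }
  }
  max(naive_p95(apply(dmat, 1, min)), naive_p95(apply(dmat, 2, min)))
}

# random (B, C, H, W) array
rand_bchw <- function(B, C, H, W, seed = NULL, lim = 3) {
  if (!is.null(seed)) set.seed(seed)
  array(stats::runif(B * C * H * W, -lim, lim), c(B, C, H, W))
}
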