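# Patchwise 2D Fourier filtering with learnable real amplitude weights.
#
# A feature map is tiled into non-overlapping P x P patches (reflect-padded up
# to the next multiple of P), each patch is transformed by an unnormalized 2D
# DFT, multiplied bin-wise by a real weight, inverse-transformed (1/P^2
# normalization) and reassembled. Weights are stored on the half-spectrum grid
# (P, P/2+1) per channel, as produced by a real FFT; the full spectrum is
# recovered by Hermitian mirroring so the filtered output is exactly real.
#
# For small P the 2D DFT of a stack of tiles is evaluated as two dense
# complex matrix products with the P x P DFT matrix, which vectorizes over
# all tiles/channels/batch at once.

.fdu_cache <- new.env(parent = emptyenv())

dft_matrix <- function(P) {
  key <- paste0("F", P)
  if (is.null(.fdu_cache[[key]])) {
    .fdu_cache[[key]] <- exp(-2i * pi * outer(0:(P - 1), 0:(P - 1)) / P)
  }
  .fdu_cache[[key]]
}

# map from full-spectrum flat index (P x P) to half-spectrum flat index
# (P x (P/2+1)) under Hermitian symmetry
half_spectrum_map <- function(P) {
  key <- paste0("M", P)
  if (is.null(.fdu_cache[[key]])) {
    Ph <- P %/% 2L
    idx <- integer(P * P)
    for (b in seq_len(P)) {
      for (a in seq_len(P)) {
        fa <- a - 1L
        fb <- b - 1L
        if (fb <= Ph) {
          # within the self-conjugate columns (DC and, for even P, Nyquist)
          # the bins (fa, fb) and (P - fa, fb) are conjugate pairs and must
          # share one amplitude weight, or the modulated spectrum would lose
          # its Hermitian symmetry
          if ((2L * fb) %% P == 0L && fa > P %/% 2L) {
            sa <- ((P - fa) %% P) + 1L
          } else {
            sa <- a
          }
          sb <- b
        } else {
          sa <- ((P - fa) %% P) + 1L
          sb <- (P - fb) + 1L
        }
        idx[a + P * (b - 1L)] <- sa + P * (sb - 1L)
      }
    }
    .fdu_cache[[key]] <- idx
  }
  .fdu_cache[[key]]
}

# batched 2D DFT of an (P, P, N) stack
dft2_stack <- function(x, P, inverse = FALSE) {
  Fm <- dft_matrix(P)
  if (inverse) Fm <- Conj(Fm)
  N <- length(x) / (P * P)
  y1 <- Fm %*% matrix(x, P)
  dim(y1) <- c(P, P, N)
  y1 <- aperm(y1, c(2L, 1L, 3L))
  y2 <- Fm %*% matrix(y1, P)
  dim(y2) <- c(P, P, N)
  y2 <- aperm(y2, c(2L, 1L, 3L))
  if (inverse) y2 <- y2 / (P * P)
  y2
}

# symmetric (reflect, edge not repeated) index extension from n to n2
reflect_idx <- function(n, n2) {
  if (n2 == n) return(seq_len(n))
  if (n == 1L) return(rep(1L, n2))
  period <- 2L * (n - 1L)
  k <- (seq_len(n2) - 1L) %% period
  as.integer(ifelse(k < n, k + 1L, period - k + 1L))
}

# adjoint of index-based padding: fold padded-region values back onto sources
fold_pad <- function(a, idx_r, idx_c, H, W) {
  d <- dim(a)
  m <- rowsum(matrix(a, d[1]), group = idx_r) # (H, W2*C*B)
  a2 <- array(m, c(H, d[2], d[3], d[4]))
  a2 <- aperm(a2, c(2L, 1L, 3L, 4L))
  m2 <- rowsum(matrix(a2, d[2]), group = idx_c) # (W, H*C*B)
  aperm(array(m2, c(W, H, d[3], d[4])), c(2L, 1L, 3L, 4L))
}

# (H2, W2, C, B) with H2, W2 multiples of P -> (P, P, Np*C*B) tile stack
patchify <- function(v, P) {
  d <- dim(v)
  nH <- d[1] %/% P
  nW <- d[2] %/% P
  dim(v) <- c(P, nH, P, nW, d[3], d[4])
  v <- aperm(v, c(1L, 3L, 2L, 4L, 5L, 6L))
  dim(v) <- c(P, P, nH * nW * d[3] * d[4])
  v
}

unpatchify <- function(v, P, H2, W2, C, B) {
  nH <- H2 %/% P
  nW <- W2 %/% P
  dim(v) <- c(P, P, nH, nW, C, B)
  v <- aperm(v, c(1L, 3L, 2L, 4L, 5L, 6L))
  dim(v) <- c(H2, W2, C, B)
  v
}

# mirror half-spectrum weights (P, P/2+1, C) to the full grid (P, P, C)
full_weights <- function(w, P) {
  C <- dim(w)[3]
  idx <- half_spectrum_map(P)
  wf <- matrix(w, ncol = C)[rep(idx, times = C) +
                              rep((seq_len(C) - 1L) * (P * (P %/% 2L + 1L)),
                                  each = P * P)]
  dim(wf) <- c(P, P, C)
  wf
}

# core linear filter: x (H, W, C, B) real, wfull (P, P, C) real
# returns list(y, xhat, mult, pad info) so the op can reuse intermediates
freq_filter_core <- function(v, wfull, P) {
  d <- dim(v)
  H <- d[1]; W <- d[2]; C <- d[3]; B <- d[4]
  H2 <- as.integer(ceiling(H / P) * P)
  W2 <- as.integer(ceiling(W / P) * P)
  idx_r <- reflect_idx(H, H2)
  idx_c <- reflect_idx(W, W2)
  vp <- v[idx_r, idx_c, , , drop = FALSE]
  xp <- patchify(vp, P)
  Np <- (H2 %/% P) * (W2 %/% P)
  xhat <- dft2_stack(xp, P)
  mult <- rep(as.vector(wfull[, , rep(seq_len(C), each = Np), drop = FALSE]),
              times = B)
  yh <- xhat * mult
  y <- Re(dft2_stack(yh, P, inverse = TRUE))
  y <- unpatchify(y, P, H2, W2, C, B)
  y <- y[seq_len(H), seq_len(W), , , drop = FALSE]
  list(y = y, xhat = xhat, mult = mult, idx_r = idx_r, idx_c = idx_c,
       H2 = H2, W2 = W2, Np = Np)
}

# tape op; x variable (H, W, C, B), w variable (P, P/2+1, C)
op_freq_filter <- function(tape, x, w, P) {
  v <- x$v
  if (any(!is.finite(v))) stop("non-finite values entering frequency filter")
  d <- dim(v)
  H <- d[1]; W <- d[2]; C <- d[3]; B <- d[4]
  wfull <- full_weights(w$v, P)
  fc <- freq_filter_core(v, wfull, P)
  xneeds <- needs_grad(x)
  make_node(tape, fc$y, function(g) {
    # zero-embed the output gradient into the padded grid (adjoint of crop)
    gz <- array(0, c(fc$H2, fc$W2, C, B))
    gz[seq_len(H), seq_len(W), , ] <- g
    gp <- patchify(gz, P)
    ghat <- dft2_stack(gp, P)
    # d loss / d W_k = Re[ xhat_k * conj(ghat_k) ] / P^2, summed over
    # tiles and batch, then folded from the full grid to the half grid
    Tm <- xhat_mul_conj(fc$xhat, ghat)
    dim(Tm) <- c(P * P, fc$Np, C, B)
    Tm <- aperm(Tm, c(1L, 3L, 2L, 4L))
    dim(Tm) <- c(P * P * C, fc$Np * B)
    s <- Re(rowSums(Tm)) / (P * P)
    acc <- rowsum(matrix(s, P * P, C), group = half_spectrum_map(P))
    # redundant (conjugate-tied) half-grid entries receive zero gradient
    gw <- matrix(0, P * (P %/% 2L + 1L), C)
    gw[as.integer(rownames(acc)), ] <- acc
    dim(gw) <- c(P, P %/% 2L + 1L, C)
    acc_grad(w, gw)
    if (xneeds) {
      # the filter is self-adjoint in x for real weights
      gy <- Re(dft2_stack(ghat * fc$mult, P, inverse = TRUE))
      gy <- unpatchify(gy, P, fc$H2, fc$W2, C, B)
      acc_grad(x, fold_pad(gy, fc$idx_r, fc$idx_c, H, W))
    }
  })
}

xhat_mul_conj <- function(a, b) a * Conj(b)

#' Patchwise frequency-domain filtering of a feature map
#'
#' Partitions a feature map into non-overlapping `P` x `P` tiles
#' (reflect-padding up to the next multiple of `P` where needed), applies a 2D
#' real FFT per tile, multiplies the spectrum bin-wise by real amplitude
#' weights, inverse-transforms, reassembles and crops back to the input size.
#' With all weights equal to 1 this is the identity map (up to floating-point
#' round-off); the operation is linear in the input for fixed weights.
#'
#' @param x numeric array of shape `(B, C, H, W)`.
#' @param P patch side length (e.g. 4, 8 or 16).
#' @param w real weight array of shape `(C, P, P/2 + 1)` on the half-spectrum
#'   grid of a real FFT; defaults to all ones (identity filter).
#' @return filtered array, same shape as `x`.
#' @export
#' @examples
#' x <- array(rnorm(2 * 3 * 8 * 8), c(2, 3, 8, 8))
#' y <- freq_filter_scale(x, P = 4)
#' max(abs(y - x)) < 1e-8 # identity at unit weights
freq_filter_scale <- function(x, P, w = NULL) {
  stopifnot(length(dim(x)) == 4L)
  C <- dim(x)[2]
  Pf <- P %/% 2L + 1L
  if (is.null(w)) w <- array(1, c(C, P, Pf))
  stopifnot(all(dim(w) == c(C, P, Pf)))
  v <- as_internal(x)
  wfull <- full_weights(aperm(w, c(2L, 3L, 1L)), P)
  as_external(freq_filter_core(v, wfull, P)$y)
}
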