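# Deterministic generator of hippocampus-like phantoms: crescent-shaped
# (bent annulus sector) low-contrast targets with blurred boundaries on a
# smooth textured background, at extreme foreground imbalance, plus the
# additive Gaussian noise perturbation used for robustness evaluation.
#
# Geometry: a crescent is the set of pixels whose distance r from a center
# lies in [R - t/2, R + t/2] and whose polar angle lies within a half-width
# phi of a random orientation. Its area is approximately 2*phi*R*t, so for a
# requested foreground fraction f the thickness is t = f*S^2 / (2*phi*R).
# The mean radius R scales with the image side and with the `curvature`
# parameter (larger curvature = tighter bend = smaller R).

#' Phantom specification
#'
#' Bundles the parameters of a synthetic hippocampus-like phantom. Defaults
#' emulate the regime of T1-weighted MRI hippocampus slices: a 256 x 256
#' image whose crescent-shaped target covers ~0.2% of the pixels, with a
#' low-contrast blurred boundary.
#'
#' @param image_size image side in pixels (default 256).
#' @param fg_fraction target foreground fraction, in (0, 0.05) (default 0.002).
#' @param curvature crescent bending parameter (>= 0.25); the crescent's mean
#'   radius is `0.15 * image_size / curvature` (default 1).
#' @param contrast foreground/background intensity gap on the 0-255 scale
#'   (default 60).
#' @param blur_sigma Gaussian width (pixels) smoothing the target boundary
#'   (default 1.5).
#' @param noise_sigma additive Gaussian noise standard deviation on the 0-255
#'   scale (default 10).
#' @param seed RNG seed; the same spec and seed give bit-identical phantoms.
#' @return a `phantom_spec` list.
#' @export
phantom_spec <- function(image_size = 256L, fg_fraction = 0.002,
                         curvature = 1, contrast = 60, blur_sigma = 1.5,
                         noise_sigma = 10, seed = 1L) {
  stopifnot(fg_fraction > 0, fg_fraction < 0.05, curvature >= 0.25,
            contrast >= 0, blur_sigma >= 0, noise_sigma >= 0,
            image_size >= 16L)
  structure(list(image_size = as.integer(image_size),
                 fg_fraction = fg_fraction, curvature = curvature,
                 contrast = contrast, blur_sigma = blur_sigma,
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Generate one phantom image/mask pair
#'
#' Draws a crescent at a randomized position and orientation; the mask is the
#' crisp crescent, the image is a smooth background texture plus
#' `contrast` x (Gaussian-blurred crescent) plus additive Gaussian noise,
#' clipped to [0, 255]. Identical specs (including seed) give bit-identical
#' output.
#'
#' @param spec a [phantom_spec()].
#' @return list with `image` (H x W matrix, 0-255), `mask` (H x W binary
#'   matrix) and `spec`.
#' @export
#' @examples
#' ph <- make_phantom(phantom_spec(image_size = 64, fg_fraction = 0.02,
#'                                 seed = 41))
#' mean(ph$mask) # close to 0.02
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  S <- spec$image_size
  with_seed(spec$seed, {
    R <- 0.15 * S / spec$curvature
    phi <- 70 / 180 * pi # angular half-width of the crescent
    t <- spec$fg_fraction * S^2 / (2 * phi * R)
    r_in <- R - t / 2
    r_out <- R + t / 2
    if (r_in < 1 || r_out > S / 2 - 2) {
      stop("infeasible fg_fraction/curvature for this image size")
    }
    margin <- ceiling(r_out) + 2
    cx <- stats::runif(1, margin, S - margin)
    cy <- stats::runif(1, margin, S - margin)
    theta0 <- stats::runif(1, -pi, pi)
    xs <- matrix(rep(seq_len(S), each = S), S) - cx   # column coords
    ys <- matrix(rep(seq_len(S), times = S), S) - cy  # row coords
    r <- sqrt(xs^2 + ys^2)
    ang <- atan2(ys, xs) - theta0
    ang <- ((ang + pi) %% (2 * pi)) - pi # wrap to (-pi, pi]
    mask <- (r >= r_in & r <= r_out & abs(ang) <= phi) + 0
    # smooth background texture: blurred white noise around a base level
    bg <- 60 + 12 * EBImage::gblur(matrix(stats::rnorm(S * S), S),
                                   sigma = S / 16)
    fg <- if (spec$blur_sigma > 0) {
      EBImage::gblur(mask, sigma = spec$blur_sigma)
    } else {
      mask
    }
    img <- bg + spec$contrast * fg
    if (spec$noise_sigma > 0) {
      img <- img + stats::rnorm(S * S, sd = spec$noise_sigma)
    }
    img <- matrix(pmin(pmax(as.numeric(img), 0), 255), S, S)
    list(image = img, mask = mask, spec = spec)
  })
}

#' Add Gaussian noise to an image
#'
#' Adds i.i.d. `N(0, sigma^2)` noise on the 0-255 intensity scale and clips to
#' `[0, 255]`; the perturbation used for noise-robustness evaluation
#' (`sigma = 15` in the reference protocol).
#'
#' @param image numeric array on the 0-255 scale.
#' @param sigma noise standard deviation (>= 0); 0 is the identity.
#' @param seed optional RNG seed.
#' @return perturbed image, same shape.
#' @export
add_gaussian_noise <- function(image, sigma, seed = NULL) {
  if (sigma < 0) stop("`sigma` must be nonnegative")
  if (sigma == 0) return(image)
  noise_fn <- function() stats::rnorm(length(image), sd = sigma)
  eps <- if (is.null(seed)) noise_fn() else with_seed(seed, noise_fn())
  out <- pmin(pmax(image + eps, 0), 255)
  dim(out) <- dim(image)
  out
}

#' Write a phantom dataset to disk
#'
#' Generates `n` phantoms (each an independent "subject" identity with its own
#' derived seed), writes paired 8-bit PNGs under `images/` and `masks/`
#' (masks as 0/255), and a `manifest.csv` with columns id, split, image_path,
#' mask_path, seed. Identities never straddle splits, mirroring a
#' subject-exclusive train/test partition.
#'
#' @param n number of phantoms (0 gives an empty manifest).
#' @param spec base [phantom_spec()]; phantom i uses seed `spec$seed * 1000 + i`.
#' @param split named fractions summing to 1, e.g.
#'   `c(train = 0.8, test = 0.2)`.
#' @param out_dir output directory (created if needed).
#' @return the manifest data frame, invisibly.
#' @export
make_dataset <- function(n, spec, split = c(train = 0.8, test = 0.2),
                         out_dir) {
  stopifnot(inherits(spec, "phantom_spec"), n >= 0)
  if (abs(sum(split) - 1) > 1e-8) stop("split fractions must sum to 1")
  if (is.null(names(split)) || any(names(split) == "")) {
    stop("split fractions must be named")
  }
  dir.create(file.path(out_dir, "images"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(out_dir, "masks"), recursive = TRUE,
             showWarnings = FALSE)
  manifest <- data.frame(id = character(0), split = character(0),
                         image_path = character(0), mask_path = character(0),
                         seed = integer(0), stringsAsFactors = FALSE)
  if (n > 0L) {
    # deterministic subject-exclusive split: counts by rounding, assigned in
    # a seed-shuffled identity order
    counts <- diff(round(cumsum(c(0, split)) * n))
    counts[length(counts)] <- n - sum(counts[-length(counts)])
    order_ids <- with_seed(spec$seed, sample.int(n))
    split_of <- rep(names(split), counts)[order(order_ids)]
    for (i in seq_len(n)) {
      id <- sprintf("phantom_%03d", i)
      sp_i <- spec
      sp_i$seed <- spec$seed * 1000L + i
      ph <- make_phantom(sp_i)
      ip <- file.path("images", paste0(id, ".png"))
      mp <- file.path("masks", paste0(id, ".png"))
      png::writePNG(ph$image / 255, file.path(out_dir, ip))
      png::writePNG(ph$mask, file.path(out_dir, mp))
      manifest <- rbind(manifest, data.frame(
        id = id, split = split_of[i], image_path = ip, mask_path = mp,
        seed = sp_i$seed, stringsAsFactors = FALSE
      ))
    }
  }
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}

#' Load an image/mask dataset from a manifest
#'
#' Reads the PNG pairs listed in a `manifest.csv` written by [make_dataset()].
#' Images are returned as `(H, W, 3)` arrays in [0, 1] (grayscale replicated
#' to three channels); masks are binarized at > 0.5.
#'
#' @param dir dataset directory containing `manifest.csv`.
#' @param split optional split name to filter on (e.g. "train").
#' @return list with `images` (list of arrays), `masks` (list of matrices) and
#'   `manifest` (data frame).
#' @export
load_manifest <- function(dir, split = NULL) {
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"),
                              stringsAsFactors = FALSE)
  if (!is.null(split)) manifest <- manifest[manifest$split %in% split, ]
  images <- list()
  masks <- list()
  for (i in seq_len(nrow(manifest))) {
    img <- png::readPNG(file.path(dir, manifest$image_path[i]))
    if (length(dim(img)) == 2L) {
      img <- array(rep(img, 3L), c(dim(img), 3L))
    } else if (dim(img)[3] > 3L) {
      img <- img[, , 1:3]
    }
    msk <- png::readPNG(file.path(dir, manifest$mask_path[i]))
    if (length(dim(msk)) == 3L) msk <- msk[, , 1]
    images[[manifest$id[i]]] <- img
    masks[[manifest$id[i]]] <- (msk > 0.5) + 0
  }
  list(images = images, masks = masks, manifest = manifest)
}
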