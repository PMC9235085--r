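# Training-time interference factors: random horizontal flip, scaling,
# rotation and additive Gaussian noise, applied consistently to the
# (truth, defect, mask) triple of a slice pair.

#' Augmentation parameters
#'
#' Defaults follow the interference factors used when training the
#' inpainting network: horizontal flip with probability 0.5, random
#' scaling in \[0.8, 1.2\], random rotation up to 11 degrees, and additive
#' Gaussian intensity noise.
#'
#' @param flip_prob horizontal flip probability in \[0, 1\].
#' @param scale_range length-2 positive `(low, high)` scaling factors.
#' @param max_rotation_deg maximum absolute rotation angle (degrees).
#' @param noise_sd Gaussian noise standard deviation in 8-bit intensity
#'   units (applied to the intensity images only, never the mask).
#' @return An `augment_params` list.
#' @export
augment_params <- function(flip_prob = 0.5, scale_range = c(0.8, 1.2),
                           max_rotation_deg = 11, noise_sd = 2) {
  if (flip_prob < 0 || flip_prob > 1) stop("flip_prob must be in [0, 1]")
  if (length(scale_range) != 2L || any(scale_range <= 0) ||
      scale_range[1] > scale_range[2])
    stop("scale_range must be positive with low <= high")
  if (max_rotation_deg < 0) stop("max_rotation_deg must be >= 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(flip_prob = flip_prob, scale_range = as.numeric(scale_range),
                 max_rotation_deg = max_rotation_deg, noise_sd = noise_sd),
            class = "augment_params")
}

# Warp an image by the affine `flip -> rotate(angle) -> scale(s)` about the
# image center, by inverse mapping. interp: "bilinear" or "nearest".
# Outside-border samples are 0 (background).
affine_warp <- function(img, angle_deg, scale, flip,
                        interp = c("bilinear", "nearest")) {
  interp <- match.arg(interp)
  nr <- nrow(img); nc <- ncol(img)
  cr <- (nr + 1) / 2; cc <- (nc + 1) / 2
  th <- angle_deg * pi / 180
  # output pixel offsets
  yo <- matrix(seq_len(nr) - cr, nr, nc)
  xo <- matrix(seq_len(nc) - cc, nr, nc, byrow = TRUE)
  # inverse map: unscale, unrotate, then unflip
  xs <- (cos(th) * xo + sin(th) * yo) / scale
  ys <- (-sin(th) * xo + cos(th) * yo) / scale
  if (flip) xs <- -xs
  sr <- ys + cr; sc <- xs + cc
  if (interp == "nearest") {
    ri <- round(sr); ci <- round(sc)
    ok <- ri >= 1 & ri <= nr & ci >= 1 & ci <= nc
    out <- matrix(0, nr, nc)
    out[ok] <- img[cbind(ri[ok], ci[ok])]
    return(out)
  }
  r0 <- floor(sr); c0 <- floor(sc)
  fr <- sr - r0; fc <- sc - c0
  get <- function(r, c) {
    ok <- r >= 1 & r <= nr & c >= 1 & c <= nc
    v <- matrix(0, nr, nc)
    v[ok] <- img[cbind(r[ok], c[ok])]
    v
  }
  get(r0, c0) * (1 - fr) * (1 - fc) + get(r0, c0 + 1) * (1 - fr) * fc +
    get(r0 + 1, c0) * fr * (1 - fc) + get(r0 + 1, c0 + 1) * fr * fc
}

#' Augment a slice pair
#'
#' Draws one (flip, scale, angle, noise field) realization and applies the
#' same geometric transform to all three images of the pair: bilinear
#' interpolation for the intensity images, nearest-neighbour for the mask
#' (so it stays binary), and additive Gaussian noise on the intensity
#' images only, clipped to \[0, 255\].
#'
#' Note that interpolation blends intensities across the mask boundary, so
#' augmented pairs (unlike freshly carved ones) need not satisfy the exact
#' `defect == truth outside mask` identity along the boundary.
#'
#' @param pair a `slice_pair`.
#' @param params an [augment_params()].
#' @param seed optional integer seed; when NULL the current RNG stream is
#'   used (as inside the training loop).
#' @return The augmented `slice_pair`.
#' @export
augment <- function(pair, params = augment_params(), seed = NULL) {
  stopifnot(inherits(pair, "slice_pair"), inherits(params, "augment_params"))
  run <- function() {
    flip <- runif(1) < params$flip_prob
    scale <- runif(1, params$scale_range[1], params$scale_range[2])
    angle <- runif(1, -params$max_rotation_deg, params$max_rotation_deg)
    identity_geom <- !flip && scale == 1 && angle == 0
    warp_img <- function(img) {
      if (identity_geom) img else affine_warp(img, angle, scale, flip,
                                              "bilinear")
    }
    truth <- warp_img(pair$truth)
    defect <- warp_img(pair$defect)
    mask <- if (identity_geom) pair$mask else
      affine_warp(pair$mask, angle, scale, flip, "nearest")
    if (params$noise_sd > 0) {
      noise <- matrix(rnorm(length(truth), 0, params$noise_sd), nrow(truth))
      truth <- pmin(pmax(truth + noise, 0), 255)
      defect <- pmin(pmax(defect + noise, 0), 255)
    }
    structure(list(truth = truth, defect = defect, mask = mask,
                   case_id = pair$case_id, slice_index = pair$slice_index),
              class = "slice_pair")
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}
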