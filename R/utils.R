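# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards. All user-facing randomness funnels
# through this so that seeds compose predictably.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Round half away from zero
#'
#' Round-half-up for positive values, the convention used both for 8-bit
#' quantization and for 2-decimal table display (unlike base `round()`,
#' which rounds half to even).
#' @param x numeric.
#' @param digits decimal places (default 0).
#' @return Rounded numeric.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

stop_if_not_scalar <- function(x, name, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || (finite && !is.finite(x)))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  invisible(x)
}

# smoothstep ramp on [0, 1]
smoothstep <- function(u) {
  u <- pmin(pmax(u, 0), 1)
  u * u * (3 - 2 * u)
}

# Bilinear resample of a numeric matrix to nr x nc (align-corners style on
# pixel centers). Used for slice resizing (e.g. 128 -> 512) and augmentation.
resize_bilinear <- function(img, nr, nc) {
  sr <- nrow(img); sc <- ncol(img)
  if (sr == nr && sc == nc) return(img)
  ry <- if (nr == 1L) rep(1, 1) else seq(1, sr, length.out = nr)
  rx <- if (nc == 1L) rep(1, 1) else seq(1, sc, length.out = nc)
  y0 <- pmin(floor(ry), sr - 1L); y0[sr == 1L] <- 1
  x0 <- pmin(floor(rx), sc - 1L); x0[sc == 1L] <- 1
  if (sr == 1L) { y0 <- rep(1L, nr); fy <- rep(0, nr) } else fy <- ry - y0
  if (sc == 1L) { x0 <- rep(1L, nc); fx <- rep(0, nc) } else fx <- rx - x0
  y1 <- pmin(y0 + 1L, sr); x1 <- pmin(x0 + 1L, sc)
  a <- img[y0, x0, drop = FALSE]; b <- img[y0, x1, drop = FALSE]
  c_ <- img[y1, x0, drop = FALSE]; d <- img[y1, x1, drop = FALSE]
  FY <- matrix(fy, nr, nc); FX <- matrix(fx, nr, nc, byrow = TRUE)
  a * (1 - FY) * (1 - FX) + b * (1 - FY) * FX + c_ * FY * (1 - FX) + d * FY * FX
}

# Nearest-neighbour resample (masks stay binary).
resize_nearest <- function(img, nr, nc) {
  sr <- nrow(img); sc <- ncol(img)
  if (sr == nr && sc == nc) return(img)
  ry <- round(seq(1, sr, length.out = nr))
  rx <- round(seq(1, sc, length.out = nc))
  img[ry, rx, drop = FALSE]
}
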