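#' CT-like volume container
#'
#' A `volume` is the universal 3D container of the pipeline: a numeric array
#' of HU-like intensities indexed `[slice, row, column]`, with physical voxel
#' `spacing = c(dx, dy, dz)` (mm) and `origin = c(x0, y0, z0)` (mm). The
#' physical coordinate of a voxel center is `origin + (index - 1) * spacing`
#' with `x` along columns, `y` along rows and `z` along slices.
#'
#' @param voxels numeric 3D array, indexed `[slice, row, column]`.
#' @param spacing numeric length-3, voxel spacing `(dx, dy, dz)` in mm, all
#'   positive.
#' @param origin numeric length-3, physical position (mm) of voxel
#'   `[1, 1, 1]`.
#' @return An object of class `volume`.
#' @examples
#' v <- volume(array(0, c(4, 4, 4)))
#' dim(v$voxels)
#' @export
volume <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop("'voxels' must be a 3D array [slice, row, column]")
  if (any(dim(voxels) < 1L)) stop("voxel grid must be non-empty")
  spacing <- as.numeric(spacing); origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("'spacing' must be three positive numbers (dx, dy, dz) in mm")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("'origin' must be three finite numbers (mm)")
  structure(list(voxels = voxels, spacing = spacing, origin = origin),
            class = "volume")
}

#' @export
print.volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<volume> %d x %d x %d voxels [slice, row, col]\n", d[1], d[2], d[3]))
  cat(sprintf("  spacing (dx, dy, dz): %.3g %.3g %.3g mm\n",
              x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  origin: (%.3g, %.3g, %.3g) mm\n",
              x$origin[1], x$origin[2], x$origin[3]))
  cat(sprintf("  intensity range: [%.4g, %.4g]\n",
              min(x$voxels), max(x$voxels)))
  invisible(x)
}

is_volume <- function(x) inherits(x, "volume")

# Physical voxel-center coordinate grids (vectors), x along columns etc.
voxel_coords <- function(vol) {
  d <- dim(vol$voxels)
  list(
    z = vol$origin[3] + (seq_len(d[1]) - 1) * vol$spacing[3],
    y = vol$origin[2] + (seq_len(d[2]) - 1) * vol$spacing[2],
    x = vol$origin[1] + (seq_len(d[3]) - 1) * vol$spacing[1]
  )
}

#' Threshold-based bone segmentation
#'
#' Voxels with intensity greater than or equal to `threshold` are marked as
#' bone. The default of 300 HU is a common cortical-bone threshold for adult
#' CT; it is configurable because clinical segmentation thresholds vary.
#'
#' @param vol a [volume()].
#' @param threshold scalar HU threshold; a voxel is bone iff
#'   `intensity >= threshold`.
#' @return A `bone_mask`: same geometry as `vol`, `voxels` is an integer
#'   array of 0/1.
#' @examples
#' v <- volume(array(c(-1000, 700), c(2, 2, 2)))
#' sum(segment_bone(v, 300)$voxels)
#' @export
segment_bone <- function(vol, threshold = 300) {
  stopifnot(is_volume(vol))
  stop_if_not_scalar(threshold, "threshold")
  m <- array(0L, dim(vol$voxels))
  m[vol$voxels >= threshold] <- 1L
  structure(list(voxels = m, spacing = vol$spacing, origin = vol$origin),
            class = "bone_mask")
}

#' Convert a volume to a stack of 8-bit grayscale slices
#'
#' Linear intensity window: `low` maps to 0, `high` to 255, values outside
#' the window are clipped, and the result is quantized with round-half-up.
#' The default window (-1000, 2000) HU places air at black and dense bone
#' near white.
#'
#' @param vol a [volume()] or a bare 3D array.
#' @param window numeric length-2 `(low, high)` HU with `low < high`.
#' @return Integer 3D array `[slice, row, column]` of values in 0..255.
#' @examples
#' v <- volume(array(c(-1000, 500, 2000, 3000), c(1, 2, 2)))
#' range(to_grayscale8(v))
#' @export
to_grayscale8 <- function(vol, window = c(-1000, 2000)) {
  vox <- if (is_volume(vol)) vol$voxels else vol
  if (!is.array(vox) || length(dim(vox)) != 3L)
    stop("input must be a volume or a 3D array")
  window <- as.numeric(window)
  if (length(window) != 2L || !all(is.finite(window)) || window[1] >= window[2])
    stop("degenerate window: need finite (low, high) with low < high")
  u <- (vox - window[1]) / (window[2] - window[1]) * 255
  u <- pmin(pmax(u, 0), 255)
  out <- array(as.integer(floor(u + 0.5)), dim(vox))
  out
}

# Map an 8-bit value (0..255) back to HU through the same window.
gray8_to_hu <- function(g, window) {
  window[1] + (g / 255) * (window[2] - window[1])
}

#' Deterministic train/test split
#'
#' Shuffles `ids` with a seeded permutation and assigns
#' `floor(test_fraction * n)` cases to the test set and the remainder to the
#' training set (the rounding rule that maps 518 cases at a 8:2 ratio to
#' 415 training and 103 testing cases).
#'
#' @param ids character or numeric vector of unique case identifiers.
#' @param test_fraction fraction in (0, 1) of cases for the test set.
#' @param seed integer seed driving the permutation.
#' @return A `dataset_split`: list with `train_ids` and `test_ids`.
#' @examples
#' s <- split_dataset(sprintf("case%03d", 1:518), 0.2, seed = 1)
#' c(train = length(s$train_ids), test = length(s$test_ids))
#' @export
split_dataset <- function(ids, test_fraction = 0.2, seed = 1) {
  if (length(ids) < 1L) stop("'ids' must be non-empty")
  if (anyDuplicated(ids)) stop("duplicate ids are not allowed")
  stop_if_not_scalar(test_fraction, "test_fraction")
  if (test_fraction <= 0 || test_fraction >= 1)
    stop("'test_fraction' must be in (0, 1)")
  n <- length(ids)
  n_test <- floor(test_fraction * n)
  perm <- with_seed(seed, sample.int(n, n))
  shuffled <- ids[perm]
  structure(list(
    train_ids = shuffled[seq_len(n - n_test)],
    test_ids = if (n_test > 0) shuffled[n - n_test + seq_len(n_test)] else ids[0]
  ), class = "dataset_split")
}

#' @export
print.dataset_split <- function(x, ...) {
  cat(sprintf("<dataset_split> %d train / %d test\n",
              length(x$train_ids), length(x$test_ids)))
  invisible(x)
}
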