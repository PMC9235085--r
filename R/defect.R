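# Artificial defect construction: parametric phantoms (sphere, cuboid,
# semi-cylinder) carved out of bone within a chosen midfacial subunit.

DEFECT_SHAPES <- c("sphere", "cuboid", "semicylinder")

#' Parametric defect specification
#'
#' @param shape one of `"sphere"`, `"cuboid"`, `"semicylinder"`.
#' @param center numeric length-3 `(x, y, z)` mm.
#' @param size shape-dependent:
#'   sphere: `list(radius = r)`;
#'   cuboid: `list(lengths = c(lx, ly, lz))` (axis-aligned full edge
#'   lengths, mm);
#'   semicylinder: `list(radius = r, length = l, axis = unit3, flat_normal
#'   = unit3)` where the carved half satisfies
#'   `(p - center) . flat_normal >= 0`.
#' @param subunit integer subunit label in 1..5.
#' @return A `defect_spec`.
#' @export
defect_spec <- function(shape, center, size, subunit) {
  shape <- match.arg(shape, DEFECT_SHAPES)
  center <- as.numeric(center)
  if (length(center) != 3L || any(!is.finite(center)))
    stop("'center' must be a finite (x, y, z) mm point")
  if (!subunit %in% 1:5) stop("'subunit' must be a label in 1..5")
  size <- as.list(size)
  if (shape == "sphere") {
    if (is.null(size$radius) || size$radius <= 0) stop("sphere needs radius > 0")
  } else if (shape == "cuboid") {
    if (is.null(size$lengths) || length(size$lengths) != 3L ||
        any(size$lengths <= 0))
      stop("cuboid needs three positive edge lengths")
  } else {
    if (is.null(size$radius) || size$radius <= 0 ||
        is.null(size$length) || size$length <= 0)
      stop("semicylinder needs radius > 0 and length > 0")
    for (f in c("axis", "flat_normal")) {
      v <- size[[f]]
      if (is.null(v) || length(v) != 3L || sum(v^2) == 0)
        stop(sprintf("semicylinder needs a nonzero 3-vector '%s'", f))
      size[[f]] <- v / sqrt(sum(v^2))
    }
    if (abs(sum(size$axis * size$flat_normal)) > 1e-8)
      stop("'flat_normal' must be perpendicular to 'axis'")
  }
  structure(list(shape = shape, center = center, size = size,
                 subunit = as.integer(subunit)),
            class = "defect_spec")
}

#' @export
print.defect_spec <- function(x, ...) {
  cat(sprintf("<defect_spec> %s in subunit %s at (%.1f, %.1f, %.1f) mm\n",
              x$shape, c("I", "II", "III", "IV", "V")[x$subunit],
              x$center[1], x$center[2], x$center[3]))
  invisible(x)
}

#' Randomly sample a defect specification within a subunit
#'
#' The defect center is drawn uniformly among voxel centers carrying the
#' requested subunit label; the shape uniformly among the three primitives;
#' sizes uniformly within `size_bounds` (interpreted as bounds on overall
#' extent: sphere and semi-cylinder diameters and cuboid edges/lengths all
#' fall in `size_bounds` mm). Deterministic given the seed.
#'
#' @param phantom a `head_phantom` (or any list with `labels`, and a
#'   `volume` providing spacing/origin).
#' @param subunit label 1..5 to place the defect in.
#' @param size_bounds numeric `(min, max)` extent in mm (default 10-30 mm).
#' @param seed integer seed.
#' @return A [defect_spec()].
#' @export
sample_defect_spec <- function(phantom, subunit, size_bounds = c(10, 30),
                               seed = 1) {
  stopifnot(!is.null(phantom$labels), is_volume(phantom$volume))
  if (!subunit %in% 1:5) stop("'subunit' must be in 1..5")
  idx <- which(phantom$labels == as.integer(subunit))
  if (length(idx) == 0L)
    stop(sprintf("subunit %d is empty in this label map", subunit))
  sp <- phantom$volume$spacing; org <- phantom$volume$origin
  d <- dim(phantom$labels)
  with_seed(seed, {
    pick <- idx[sample.int(length(idx), 1L)]
    ai <- arrayInd(pick, d) # (slice, row, col)
    center <- c(org[1] + (ai[3] - 1) * sp[1],
                org[2] + (ai[2] - 1) * sp[2],
                org[3] + (ai[1] - 1) * sp[3])
    shape <- DEFECT_SHAPES[sample.int(3L, 1L)]
    size <- switch(shape,
      sphere = list(radius = runif(1, size_bounds[1], size_bounds[2]) / 2),
      cuboid = list(lengths = runif(3, size_bounds[1], size_bounds[2])),
      semicylinder = {
        ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
        ref <- if (abs(ax[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
        fn <- ref - sum(ref * ax) * ax; fn <- fn / sqrt(sum(fn^2))
        ang <- runif(1, 0, 2 * pi)
        fn2 <- pracma_cross(ax, fn)
        list(radius = runif(1, size_bounds[1], size_bounds[2]) / 2,
             length = runif(1, size_bounds[1], size_bounds[2]),
             axis = ax,
             flat_normal = cos(ang) * fn + sin(ang) * fn2)
      })
    defect_spec(shape, center, size, subunit)
  })
}

#' Serialize / deserialize a defect spec as JSON
#'
#' @param spec a [defect_spec()].
#' @param path JSON file path.
#' @return `write_defect_spec()` returns `path` invisibly;
#'   `read_defect_spec()` returns the [defect_spec()].
#' @export
write_defect_spec <- function(spec, path) {
  stopifnot(inherits(spec, "defect_spec"))
  jsonlite::write_json(unclass(spec), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_defect_spec
#' @export
read_defect_spec <- function(path) {
  s <- jsonlite::read_json(path, simplifyVector = TRUE)
  defect_spec(s$shape, s$center, s$size, s$subunit)
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Analytic membership of voxel centers in a defect shape.
# X, Y, Z are coordinate arrays of identical dim.
.defect_membership <- function(spec, X, Y, Z) {
  dx <- X - spec$center[1]; dy <- Y - spec$center[2]; dz <- Z - spec$center[3]
  switch(spec$shape,
    sphere = dx^2 + dy^2 + dz^2 <= spec$size$radius^2,
    cuboid = abs(dx) <= spec$size$lengths[1] / 2 &
             abs(dy) <= spec$size$lengths[2] / 2 &
             abs(dz) <= spec$size$lengths[3] / 2,
    semicylinder = {
      ax <- spec$size$axis; fn <- spec$size$flat_normal
      t <- dx * ax[1] + dy * ax[2] + dz * ax[3]
      rx <- dx - t * ax[1]; ry <- dy - t * ax[2]; rz <- dz - t * ax[3]
      abs(t) <= spec$size$length / 2 &
        rx^2 + ry^2 + rz^2 <= spec$size$radius^2 &
        (rx * fn[1] + ry * fn[2] + rz * fn[3]) >= 0
    })
}

#' Carve an artificial defect out of a volume
#'
#' Voxels whose centers lie inside the analytic defect shape AND inside the
#' bone mask are set to `fill_hu` (soft-tissue intensity by default,
#' mimicking resected bone with residual soft tissue); all other voxels are
#' untouched. No partial-volume weighting: membership is a pure
#' voxel-center-inside-shape test.
#'
#' @param vol a [volume()] (the normal volume).
#' @param bone its [segment_bone()] mask.
#' @param spec a [defect_spec()].
#' @param fill_hu intensity for carved voxels (default 40 HU).
#' @return List with `volume` (the defect volume) and `mask` (integer 3D
#'   array, 1 = carved voxel).
#' @export
carve_defect <- function(vol, bone, spec, fill_hu = 40) {
  stopifnot(is_volume(vol), inherits(bone, "bone_mask"),
            inherits(spec, "defect_spec"))
  if (!identical(dim(vol$voxels), dim(bone$voxels)))
    stop("volume and bone mask shapes differ")
  d <- dim(vol$voxels)
  co <- voxel_coords(vol)
  # reject shapes entirely outside the grid bounding box
  ext <- switch(spec$shape,
    sphere = rep(spec$size$radius, 3),
    cuboid = spec$size$lengths / 2,
    semicylinder = rep(max(spec$size$radius, spec$size$length / 2), 3))
  lo <- c(min(co$x), min(co$y), min(co$z)); hi <- c(max(co$x), max(co$y), max(co$z))
  if (any(spec$center + ext < lo) || any(spec$center - ext > hi))
    stop("defect shape lies entirely outside the volume grid")
  Z <- array(rep(co$z, times = d[2] * d[3]), d)
  Y <- array(rep(rep(co$y, each = d[1]), times = d[3]), d)
  X <- array(rep(co$x, each = d[1] * d[2]), d)
  inside <- .defect_membership(spec, X, Y, Z)
  carved <- inside & bone$voxels == 1L
  out <- vol$voxels
  out[carved] <- fill_hu
  mask <- array(0L, d); mask[carved] <- 1L
  list(volume = volume(out, vol$spacing, vol$origin), mask = mask)
}

#' Build aligned (truth, defect, mask) slice pairs
#'
#' Emits one `slice_pair` per axial slice intersecting the 3D defect mask
#' (or all slices with `all_slices = TRUE`): the normal and defect slices
#' converted to 8-bit via [to_grayscale8()] with a shared window, plus the
#' binary mask slice. Optionally resamples to `resolution` (bilinear for
#' images, nearest-neighbour for the mask), e.g. 512 for full-scale runs.
#'
#' @param normal,defect [volume()]s of identical shape.
#' @param mask3d integer/logical 3D array marking carved voxels.
#' @param window grayscale window, see [to_grayscale8()].
#' @param case_id identifier stored in each pair.
#' @param all_slices emit every slice, not only mask-intersecting ones.
#' @param resolution optional target in-plane resolution (single integer).
#' @return List of `slice_pair` objects (fields `truth`, `defect`, `mask`,
#'   `case_id`, `slice_index`).
#' @export
make_slice_pairs <- function(normal, defect, mask3d,
                             window = c(-1000, 2000), case_id = "case",
                             all_slices = FALSE, resolution = NULL) {
  stopifnot(is_volume(normal), is_volume(defect))
  if (!identical(dim(normal$voxels), dim(defect$voxels)) ||
      !identical(dim(normal$voxels), dim(mask3d)))
    stop("normal, defect and mask arrays must have identical shape")
  t8 <- to_grayscale8(normal, window)
  d8 <- to_grayscale8(defect, window)
  d <- dim(mask3d)
  slices <- if (all_slices) seq_len(d[1]) else
    which(apply(mask3d, 1, function(m) any(m != 0)))
  out <- vector("list", length(slices))
  for (i in seq_along(slices)) {
    s <- slices[i]
    truth <- matrix(as.numeric(t8[s, , ]), d[2], d[3])
    def <- matrix(as.numeric(d8[s, , ]), d[2], d[3])
    msk <- matrix(as.numeric(mask3d[s, , ] != 0), d[2], d[3])
    if (!is.null(resolution)) {
      truth <- round(resize_bilinear(truth, resolution, resolution))
      def <- round(resize_bilinear(def, resolution, resolution))
      msk <- resize_nearest(msk, resolution, resolution)
      # recomposite so interpolation cannot leak carved intensities
      # across the mask boundary: defect == truth wherever mask = 0
      def[msk == 0] <- truth[msk == 0]
    }
    out[[i]] <- slice_pair(truth, def, msk, case_id = case_id,
                           slice_index = s)
  }
  out
}

#' Build a standard synthetic slice-pair set from one phantom
#'
#' Convenience wrapper tying the phantom, bone segmentation, defect
#' sampling and slice-pair construction together: carves one seeded
#' defect per requested subunit out of a default head phantom and pools
#' the resulting mask-intersecting slice pairs. This is the desk-scale
#' training-set generator used by the examples and the acceptance
#' experiments.
#'
#' @param subunits integer vector of subunit labels to carve (one defect
#'   each).
#' @param size_bounds defect extent bounds in mm.
#' @param grid phantom voxel grid.
#' @param seed master seed (defect draws derive from it).
#' @return List of `slice_pair`s.
#' @export
phantom_slice_pairs <- function(subunits = c(3, 4, 5),
                                size_bounds = c(10, 20),
                                grid = c(64, 64, 64), seed = 1) {
  ph <- generate_head_phantom(head_phantom_config(grid = grid))
  bm <- segment_bone(ph$volume, 300)
  out <- list()
  for (i in seq_along(subunits)) {
    sp <- sample_defect_spec(ph, subunits[i], size_bounds,
                             seed = seed * 100 + i)
    cd <- carve_defect(ph$volume, bm, sp)
    out <- c(out, make_slice_pairs(ph$volume, cd$volume, cd$mask,
                                   case_id = sprintf("case%02d", i)))
  }
  out
}

#' Construct a slice pair
#'
#' @param truth,defect numeric matrices of 8-bit values (0..255).
#' @param mask binary matrix of the same shape (1 = carved region).
#' @param case_id case identifier.
#' @param slice_index axial slice index the pair came from.
#' @return A `slice_pair`.
#' @export
slice_pair <- function(truth, defect, mask, case_id = "case",
                       slice_index = 1L) {
  if (!identical(dim(truth), dim(defect)) || !identical(dim(truth), dim(mask)))
    stop("truth, defect and mask must have identical shape")
  if (!all(mask %in% c(0, 1))) stop("mask must be binary")
  if (any(defect[mask == 0] != truth[mask == 0]))
    stop("defect must equal truth wherever mask = 0")
  structure(list(truth = truth, defect = defect, mask = mask,
                 case_id = case_id, slice_index = as.integer(slice_index)),
            class = "slice_pair")
}

#' Write slice pairs as PNG triplets with a manifest
#'
#' @param pairs list of `slice_pair`s.
#' @param dir output directory.
#' @param extra optional data.frame of per-pair metadata columns (recycled
#'   checks not applied; must have one row per pair).
#' @return Invisibly, the manifest data.frame (also written as
#'   `manifest.csv`).
#' @export
write_slice_pairs <- function(pairs, dir, extra = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  rows <- lapply(seq_along(pairs), function(i) {
    p <- pairs[[i]]
    stub <- sprintf("%s_s%04d", p$case_id, p$slice_index)
    write_gray8(p$truth, file.path(dir, paste0(stub, "_truth.png")))
    write_gray8(p$defect, file.path(dir, paste0(stub, "_defect.png")))
    write_gray8(p$mask * 255, file.path(dir, paste0(stub, "_mask.png")))
    data.frame(case_id = p$case_id, slice_index = p$slice_index,
               stub = stub, stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  if (!is.null(extra)) manifest <- cbind(manifest, extra)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}
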