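# Reconstruction accuracy metrics: cosine similarity on 8-bit images,
# symmetric mean surface error between registered meshes, and the
# mirror-symmetry reference surface for unilateral defects.

#' Cosine similarity between two images
#'
#' Both images are flattened to vectors; the result is
#' `dot(a, b) / (||a|| * ||b||)`: 1 for identical direction, 0 for
#' disjoint support. Symmetric and invariant to positive rescaling of
#' either image.
#'
#' @param a,b numeric matrices (8-bit slice images) of identical shape.
#' @return Scalar in [-1, 1].
#' @export
cosine_similarity <- function(a, b) {
  if (!identical(dim(a), dim(b))) stop("images must have identical shape")
  a <- as.numeric(a); b <- as.numeric(b)
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0)
    stop("cosine similarity undefined for an all-zero image")
  sum(a * b) / (na * nb)
}

#' Aggregate per-slice similarities to one per-case value
#'
#' Unweighted mean by default; mask-area weights may be supplied to weight
#' slices by defect size.
#'
#' @param values numeric vector of per-slice similarities.
#' @param weights optional non-negative weights (e.g. mask areas).
#' @return Scalar aggregate.
#' @export
aggregate_case_similarity <- function(values, weights = NULL) {
  if (length(values) == 0) stop("no slice values to aggregate")
  if (is.null(weights)) return(mean(values))
  if (length(weights) != length(values) || any(weights < 0))
    stop("weights must be non-negative and match values in length")
  sum(values * weights) / sum(weights)
}

#' Symmetric mean surface error between two meshes (mm)
#'
#' Mean unsigned point-to-triangle distance from the vertices of `recon`
#' to the `reference` surface, averaged with the reverse direction
#' (`mode = "symmetric"`, default). `mode = "one_sided"` reports only
#' recon-to-reference, matching deviation tools that measure a test
#' surface against a reference. An optional `region` predicate (a function
#' of an n x 3 coordinate matrix returning a logical vector) restricts the
#' error to a delineated region of interest, e.g. the defect area.
#'
#' Surfaces are compared as-is: apply [register_rigid()] first if they are
#' not already aligned.
#'
#' @param recon,reference [surface_mesh()]es.
#' @param region optional predicate on vertex coordinates.
#' @param mode `"symmetric"` (default) or `"one_sided"`.
#' @return Scalar mean distance in mm.
#' @export
mean_surface_error <- function(recon, reference, region = NULL,
                               mode = c("symmetric", "one_sided")) {
  mode <- match.arg(mode)
  dir_error <- function(from, to) {
    v <- from$vertices
    if (!is.null(region)) {
      keep <- region(v)
      if (!any(keep)) stop("empty region after restriction")
      v <- v[keep, , drop = FALSE]
    }
    mean(.closest_point_mesh(v, to$vertices, to$triangles)$distance)
  }
  d1 <- dir_error(recon, reference)
  if (mode == "one_sided") return(d1)
  d2 <- dir_error(reference, recon)
  (d1 + d2) / 2
}

# Least-squares plane through >= 3 points; returns point (centroid) and
# unit normal. Errors on (near-)collinear input.
fit_plane <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 3) stop("need at least 3 landmarks")
  ctr <- colMeans(points)
  X <- sweep(points, 2, ctr)
  s <- svd(X)
  if (s$d[2] < 1e-9 * max(s$d[1], 1))
    stop("landmarks are collinear: no unique plane")
  list(point = ctr, normal = s$v[, 3])
}

#' Mirror-technology reference surface
#'
#' Builds the classic mirror reference for unilateral defects: fit the
#' midsagittal plane to the landmarks (least squares), reflect the bone
#' surface across it, and (optionally) refine the reflected surface onto
#' the intact anatomy with rigid ICP - the in-package surrogate for the
#' fine manual adjustment a surgeon would perform. Vertices inside
#' `defect_region` are excluded from driving the refinement so the defect
#' cannot bias the alignment.
#'
#' @param bone a `bone_mask` (see [segment_bone()]) or a [surface_mesh()].
#' @param landmarks n x 3 matrix (n >= 3, non-collinear) of midsagittal
#'   landmarks in mm.
#' @param defect_region optional predicate on vertex coordinates marking
#'   the defect area (excluded from refinement).
#' @param refine run the ICP refinement (default TRUE).
#' @param ... passed to [extract_surface()] when `bone` is a mask.
#' @return The reflected (and refined) [surface_mesh()], with the fitted
#'   plane in attributes `plane_point` / `plane_normal`.
#' @export
mirror_reference <- function(bone, landmarks, defect_region = NULL,
                             refine = TRUE, ...) {
  plane <- fit_plane(landmarks)
  surf <- if (inherits(bone, "surface_mesh")) bone else
    extract_surface(bone, ...)
  mirrored <- reflect_mesh(surf, plane$point, plane$normal)
  if (refine) {
    subset <- NULL
    if (!is.null(defect_region)) {
      keep <- !defect_region(mirrored$vertices)
      if (sum(keep) >= 3) subset <- keep
    }
    tf <- register_rigid(mirrored, surf, subset = subset)
    mirrored <- apply_transform(tf, mirrored)
  }
  attr(mirrored, "plane_point") <- plane$point
  attr(mirrored, "plane_normal") <- plane$normal
  mirrored
}

#' Evaluate one reconstructed case
#'
#' Computes the two accuracy measures of the pipeline for a reconstructed
#' volume against its reference: the per-slice cosine similarity of the
#' 8-bit images over mask-intersecting slices (aggregated with
#' [aggregate_case_similarity()]) and the registered symmetric mean
#' surface error (mm) between the bone surfaces.
#'
#' @param reference the ground-truth [volume()].
#' @param recon the reconstructed [volume()].
#' @param mask3d 3D defect mask; slices intersecting it enter the cosine
#'   average.
#' @param window grayscale window for the 8-bit conversion.
#' @param threshold bone segmentation threshold (HU).
#' @param register run rigid ICP before measuring the surface error.
#' @param region optional region predicate for the surface error.
#' @param case_id,defect_class bookkeeping fields copied to the result.
#' @return A `similarity_result`: list with `case_id`, `defect_class`,
#'   `cosine`, `per_slice`, `mean_error_mm`.
#' @export
evaluate_reconstruction <- function(reference, recon, mask3d,
                                    window = c(-1000, 2000),
                                    threshold = 300, register = TRUE,
                                    region = NULL, case_id = "case",
                                    defect_class = "artificial") {
  stopifnot(is_volume(reference), is_volume(recon))
  t8 <- to_grayscale8(reference, window)
  r8 <- to_grayscale8(recon, window)
  slices <- which(apply(mask3d, 1, function(m) any(m != 0)))
  if (length(slices) == 0) stop("defect mask is empty")
  per_slice <- vapply(slices, function(s)
    cosine_similarity(r8[s, , ], t8[s, , ]), numeric(1))
  cosine <- aggregate_case_similarity(per_slice)

  ref_mesh <- extract_surface(segment_bone(reference, threshold))
  rec_mesh <- extract_surface(segment_bone(recon, threshold))
  if (register) {
    tf <- register_rigid(rec_mesh, ref_mesh)
    rec_mesh <- apply_transform(tf, rec_mesh)
  }
  err <- mean_surface_error(rec_mesh, ref_mesh, region = region)
  structure(list(case_id = case_id, defect_class = defect_class,
                 cosine = cosine, per_slice = per_slice,
                 mean_error_mm = err),
            class = "similarity_result")
}

#' @export
print.similarity_result <- function(x, ...) {
  cat(sprintf("<similarity_result> %s (%s): cosine %.4f, mean error %.4f mm\n",
              x$case_id, x$defect_class, x$cosine, x$mean_error_mm))
  invisible(x)
}
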