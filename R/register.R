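# Rigid transforms and iterative-closest-point surface registration.

#' Rigid transform (rotation + translation)
#'
#' @param rotation 3 x 3 orthonormal matrix with determinant +1.
#' @param translation numeric length-3 (mm).
#' @return A `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  if (!all(dim(rotation) == c(3, 3)) || length(translation) != 3L)
    stop("need a 3x3 rotation and length-3 translation")
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-8)
    stop("rotation must be orthonormal (R'R = I within 1e-8)")
  if (det(rotation) <= 0) stop("rotation must have det +1 (no reflections)")
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  ang <- rotation_angle_deg(x$rotation)
  cat(sprintf(
    "<rigid_transform> rotation %.3f deg, translation (%.3f, %.3f, %.3f) mm\n",
    ang, x$translation[1], x$translation[2], x$translation[3]))
  invisible(x)
}

# Rotation angle in degrees from a rotation matrix.
rotation_angle_deg <- function(R) {
  c_ <- (sum(diag(R)) - 1) / 2
  acos(pmin(pmax(c_, -1), 1)) * 180 / pi
}

#' Apply a rigid transform to points or a mesh
#' @param transform a [rigid_transform()].
#' @param x n x 3 matrix of points or a [surface_mesh()].
#' @return Transformed points / mesh.
#' @export
apply_transform <- function(transform, x) {
  if (inherits(x, "surface_mesh")) {
    return(surface_mesh(apply_transform(transform, x$vertices), x$triangles))
  }
  x <- as.matrix(x)
  x %*% t(transform$rotation) +
    matrix(transform$translation, nrow(x), 3, byrow = TRUE)
}

#' Compose two rigid transforms (`b` applied after `a`)
#' @param a,b [rigid_transform()]s.
#' @return The composition as a `rigid_transform`.
#' @export
compose_transform <- function(b, a) {
  rigid_transform(b$rotation %*% a$rotation,
                  as.numeric(b$rotation %*% a$translation) + b$translation)
}

#' Write a rigid transform as a 4x4 matrix in JSON
#' @param transform a [rigid_transform()].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_transform_json <- function(transform, path) {
  m <- rbind(cbind(transform$rotation, transform$translation), c(0, 0, 0, 1))
  jsonlite::write_json(list(matrix = m), path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

# Rotation matrix from an axis-angle vector (Rodrigues formula).
rodrigues <- function(w) {
  th <- sqrt(sum(w^2))
  if (th < 1e-14) return(diag(3))
  k <- w / th
  K <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# Least-squares rigid fit mapping points P onto Q (Kabsch/Umeyama, no scale).
kabsch <- function(P, Q, weights = NULL) {
  if (is.null(weights)) weights <- rep(1, nrow(P))
  w <- weights / sum(weights)
  cp <- colSums(P * w); cq <- colSums(Q * w)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  H <- t(Pc * w) %*% Qc
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  R <- s$v %*% D %*% t(s$u)
  t <- cq - as.numeric(R %*% cp)
  rigid_transform(R, t)
}

#' Rigid ICP registration of two surface meshes
#'
#' Iterative closest point: at each iteration the (optionally subsetted)
#' vertices of `moving`, under the current transform, are matched to their
#' closest points on the `fixed` surface (point-to-triangle, not
#' point-to-vertex), and a linearized point-to-plane rigid increment is
#' solved in closed form (the point-to-plane objective converges much
#' faster than point-to-point updates because tangential sliding is
#' unpenalized). Iteration stops when the relative improvement of the
#' mean squared closest-point distance falls below `tol` or after
#' `max_iter` iterations; the best iterate is returned either way.
#'
#' @param moving,fixed [surface_mesh()]s.
#' @param init initial [rigid_transform()] (identity by default).
#' @param subset optional logical/integer vector selecting which `moving`
#'   vertices participate (e.g. to exclude a defect region from driving
#'   the alignment).
#' @param max_iter maximum iterations (default 100).
#' @param tol relative-improvement stopping threshold (default 1e-6);
#'   iteration also stops once the mean squared distance falls below
#'   1e-14 mm^2.
#' @param max_points cap on the number of moving vertices driving the
#'   alignment (deterministic even subsample; default 2000). Dense meshes
#'   gain nothing from more correspondences.
#' @return A `rigid_transform` with attributes `converged` (logical),
#'   `iterations`, and `rms` (final root-mean-square distance, mm).
#' @export
register_rigid <- function(moving, fixed, init = rigid_transform(),
                           subset = NULL, max_iter = 100, tol = 1e-6,
                           max_points = 2000) {
  stopifnot(inherits(moving, "surface_mesh"), inherits(fixed, "surface_mesh"))
  if (nrow(moving$vertices) == 0 || nrow(fixed$vertices) == 0)
    stop("both meshes must be non-empty")
  P0 <- moving$vertices
  if (!is.null(subset)) P0 <- P0[subset, , drop = FALSE]
  if (nrow(P0) < 3) stop("need at least 3 participating vertices")
  if (nrow(P0) > max_points) {
    keep <- unique(round(seq(1, nrow(P0), length.out = max_points)))
    P0 <- P0[keep, , drop = FALSE]
  }
  # unit normals of the fixed mesh triangles (orientation irrelevant)
  fv <- fixed$vertices; ft <- fixed$triangles
  e1 <- fv[ft[, 2], , drop = FALSE] - fv[ft[, 1], , drop = FALSE]
  e2 <- fv[ft[, 3], , drop = FALSE] - fv[ft[, 1], , drop = FALSE]
  fn <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  fn <- fn / pmax(sqrt(rowSums(fn^2)), 1e-30)

  cur <- init
  prev_mse <- Inf
  converged <- FALSE
  it <- 0L
  best <- cur; best_mse <- Inf
  while (it < max_iter) {
    it <- it + 1L
    P <- apply_transform(cur, P0)
    cp <- .closest_point_mesh(P, fixed$vertices, fixed$triangles)
    mse <- mean(cp$distance^2)
    if (mse < best_mse) { best <- cur; best_mse <- mse }
    if (mse < 1e-14 ||
        (is.finite(prev_mse) &&
         (prev_mse - mse) <= tol * max(prev_mse, .Machine$double.eps))) {
      converged <- TRUE
      break
    }
    prev_mse <- mse
    # point-to-plane increment: minimize sum( (n.(p + w x p + t - q))^2 )
    n <- fn[cp$triangle, , drop = FALSE]
    r <- rowSums((P - cp$closest) * n)
    a <- cbind(P[, 2] * n[, 3] - P[, 3] * n[, 2],
               P[, 3] * n[, 1] - P[, 1] * n[, 3],
               P[, 1] * n[, 2] - P[, 2] * n[, 1])
    J <- cbind(a, n)
    A <- crossprod(J) + diag(1e-10, 6)
    x <- solve(A, -as.numeric(crossprod(J, r)))
    inc <- rigid_transform(rodrigues(x[1:3]), x[4:6])
    cur <- compose_transform(inc, cur)
  }
  out <- best
  attr(out, "converged") <- converged
  attr(out, "iterations") <- it
  attr(out, "rms") <- sqrt(best_mse)
  out
}
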