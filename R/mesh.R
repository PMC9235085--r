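# Triangulated bone surfaces: isosurface extraction, areas, watertightness,
# STL/PLY I/O.

#' Construct a surface mesh
#'
#' @param vertices numeric n x 3 matrix of mm coordinates (x, y, z).
#' @param triangles integer m x 3 matrix of 1-based vertex indices.
#' @return A `surface_mesh`.
#' @export
surface_mesh <- function(vertices, triangles) {
  vertices <- as.matrix(vertices); storage.mode(vertices) <- "double"
  triangles <- as.matrix(triangles); storage.mode(triangles) <- "integer"
  if (ncol(vertices) != 3L || ncol(triangles) != 3L)
    stop("vertices and triangles must have 3 columns")
  if (any(!is.finite(vertices))) stop("vertex coordinates must be finite")
  if (nrow(triangles) > 0 &&
      (min(triangles) < 1L || max(triangles) > nrow(vertices)))
    stop("triangle indices out of range")
  structure(list(vertices = vertices, triangles = triangles),
            class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("<surface_mesh> %d vertices, %d triangles, area %.2f mm^2\n",
              nrow(x$vertices), nrow(x$triangles), mesh_area(x)))
  invisible(x)
}

#' Total surface area of a mesh (mm^2)
#' @param mesh a [surface_mesh()].
#' @return Scalar area.
#' @export
mesh_area <- function(mesh) {
  v <- mesh$vertices; tr <- mesh$triangles
  if (nrow(tr) == 0) return(0)
  a <- v[tr[, 2], , drop = FALSE] - v[tr[, 1], , drop = FALSE]
  b <- v[tr[, 3], , drop = FALSE] - v[tr[, 1], , drop = FALSE]
  cx <- a[, 2] * b[, 3] - a[, 3] * b[, 2]
  cy <- a[, 3] * b[, 1] - a[, 1] * b[, 3]
  cz <- a[, 1] * b[, 2] - a[, 2] * b[, 1]
  sum(sqrt(cx^2 + cy^2 + cz^2)) / 2
}

#' Check that every edge is shared by exactly two triangles
#' @param mesh a [surface_mesh()].
#' @return Logical.
#' @export
is_watertight <- function(mesh) {
  tr <- mesh$triangles
  if (nrow(tr) == 0) return(FALSE)
  e <- rbind(tr[, c(1, 2)], tr[, c(2, 3)], tr[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  all(table(key) == 2L)
}

# Separable Gaussian smoothing of a 3D array (kernel truncated at 3 sigma,
# zero boundary condition). sigma in voxels, may be 0 (identity).
gauss_smooth3 <- function(a, sigma) {
  if (sigma <= 0) return(a)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2)); k <- k / sum(k)
  d <- dim(a)
  smooth_axis <- function(a, axis) {
    d <- dim(a)
    n <- d[axis]
    # band matrix of the kernel with zero-padding boundaries
    K <- matrix(0, n, n)
    for (o in -r:r) {
      idx <- seq_len(n)
      j <- idx + o
      ok <- j >= 1 & j <= n
      K[cbind(idx[ok], j[ok])] <- K[cbind(idx[ok], j[ok])] + k[o + r + 1]
    }
    perm <- c(axis, setdiff(1:3, axis))
    ap <- aperm(a, perm)
    m <- matrix(ap, nrow = n)
    sm <- K %*% m
    out <- array(sm, dim = d[perm])
    aperm(out, order(perm))
  }
  for (ax in 1:3) a <- smooth_axis(a, ax)
  a
}

#' Extract a closed triangulated isosurface from a binary mask
#'
#' Marching tetrahedra (6-tet decomposition of each grid cube) at
#' `level = 0.5`, applied to the mask optionally pre-smoothed with a small
#' Gaussian (`smooth_sigma`, voxels) for sub-voxel surface placement. If
#' smoothing would make the surface vanish (tiny components), the raw
#' binary field is used instead. The volume border is padded so every
#' surface is closed. Degenerate (zero-area) triangles are dropped.
#'
#' @param mask 3D binary array, or a `bone_mask`.
#' @param spacing voxel spacing `(dx, dy, dz)` mm (taken from the mask
#'   object when available).
#' @param origin physical origin (mm).
#' @param level iso level (default 0.5).
#' @param smooth_sigma Gaussian pre-smoothing in voxels (default 1.2; 0
#'   disables).
#' @return A [surface_mesh()] with vertices in mm.
#' @export
extract_surface <- function(mask, spacing = NULL, origin = NULL,
                            level = 0.5, smooth_sigma = 1.2) {
  if (inherits(mask, "bone_mask")) {
    if (is.null(spacing)) spacing <- mask$spacing
    if (is.null(origin)) origin <- mask$origin
    mask <- mask$voxels
  }
  if (is.null(spacing)) spacing <- c(1, 1, 1)
  if (is.null(origin)) origin <- c(0, 0, 0)
  if (!is.array(mask) || length(dim(mask)) != 3L)
    stop("mask must be a 3D array")
  m <- array(as.numeric(mask != 0), dim(mask))
  if (sum(m) == 0) stop("empty mask: no surface to extract")
  field <- gauss_smooth3(m, smooth_sigma)
  if (!any(field > level)) field <- m # smoothing erased the component
  # pad with background so surfaces at the volume border close
  d <- dim(field)
  padded <- array(0, d + 2L)
  padded[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- field
  res <- .mt_isosurface(padded, level)
  v <- res$vertices # (i1, i2, i3) padded 0-based index space
  # unpad (-1) and convert to mm: i1 -> z, i2 -> y, i3 -> x
  xyz <- cbind(origin[1] + (v[, 3] - 1) * spacing[1],
               origin[2] + (v[, 2] - 1) * spacing[2],
               origin[3] + (v[, 1] - 1) * spacing[3])
  mesh <- surface_mesh(xyz, res$triangles)
  drop_degenerate_triangles(mesh)
}

drop_degenerate_triangles <- function(mesh, eps = 1e-12) {
  v <- mesh$vertices; tr <- mesh$triangles
  if (nrow(tr) == 0) return(mesh)
  a <- v[tr[, 2], , drop = FALSE] - v[tr[, 1], , drop = FALSE]
  b <- v[tr[, 3], , drop = FALSE] - v[tr[, 1], , drop = FALSE]
  cx <- a[, 2] * b[, 3] - a[, 3] * b[, 2]
  cy <- a[, 3] * b[, 1] - a[, 1] * b[, 3]
  cz <- a[, 1] * b[, 2] - a[, 2] * b[, 1]
  area2 <- sqrt(cx^2 + cy^2 + cz^2)
  surface_mesh(v, tr[area2 > eps, , drop = FALSE])
}

#' Reflect a mesh across a plane
#'
#' @param mesh a [surface_mesh()].
#' @param point a point on the plane (mm).
#' @param normal plane normal (need not be unit length).
#' @return The reflected [surface_mesh()] (triangle winding flipped so
#'   orientation is preserved).
#' @export
reflect_mesh <- function(mesh, point, normal) {
  n <- normal / sqrt(sum(normal^2))
  v <- mesh$vertices
  dist <- (v - matrix(point, nrow(v), 3, byrow = TRUE)) %*% n
  v2 <- v - 2 * dist %*% t(n)
  surface_mesh(v2, mesh$triangles[, c(1, 3, 2), drop = FALSE])
}

#' Write a mesh as ASCII STL
#' @param mesh a [surface_mesh()].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_stl <- function(mesh, path) {
  v <- mesh$vertices; tr <- mesh$triangles
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("solid mesh", con)
  for (i in seq_len(nrow(tr))) {
    p <- v[tr[i, ], , drop = FALSE]
    n <- pracma_cross(p[2, ] - p[1, ], p[3, ] - p[1, ])
    nn <- sqrt(sum(n^2)); if (nn > 0) n <- n / nn
    writeLines(c(
      sprintf("  facet normal %.9g %.9g %.9g", n[1], n[2], n[3]),
      "    outer loop",
      sprintf("      vertex %.9g %.9g %.9g", p[, 1], p[, 2], p[, 3]),
      "    endloop",
      "  endfacet"), con)
  }
  writeLines("endsolid mesh", con)
  invisible(path)
}

#' Read an ASCII STL file
#'
#' Vertices are de-duplicated exactly (by coordinate string), so meshes
#' written by [write_stl()] round-trip with shared vertices.
#' @param path STL path.
#' @return A [surface_mesh()].
#' @export
read_stl <- function(path) {
  lines <- readLines(path)
  vl <- grep("^\\s*vertex ", lines, value = TRUE)
  if (length(vl) %% 3L != 0L) stop("malformed STL: vertex count not divisible by 3")
  m <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"), function(p)
    as.numeric(p[2:4])))
  key <- paste(m[, 1], m[, 2], m[, 3])
  uk <- !duplicated(key)
  ids <- match(key, key[uk])
  verts <- m[uk, , drop = FALSE]
  tris <- matrix(ids, ncol = 3, byrow = TRUE)
  surface_mesh(verts, tris)
}

#' Write a mesh as ASCII PLY
#' @param mesh a [surface_mesh()].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_ply <- function(mesh, path) {
  v <- mesh$vertices; tr <- mesh$triangles
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(v)),
               "property double x", "property double y", "property double z",
               sprintf("element face %d", nrow(tr)),
               "property list uchar int vertex_indices", "end_header"), con)
  writeLines(sprintf("%.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]), con)
  writeLines(sprintf("3 %d %d %d", tr[, 1] - 1L, tr[, 2] - 1L, tr[, 3] - 1L), con)
  invisible(path)
}

#' Read an ASCII PLY file written by [write_ply()]
#' @param path PLY path.
#' @return A [surface_mesh()].
#' @export
read_ply <- function(path) {
  lines <- readLines(path)
  nv <- as.integer(sub("element vertex ", "", grep("^element vertex", lines, value = TRUE)))
  nf <- as.integer(sub("element face ", "", grep("^element face", lines, value = TRUE)))
  hdr <- which(lines == "end_header")
  vm <- do.call(rbind, lapply(strsplit(lines[hdr + seq_len(nv)], "\\s+"),
                              as.numeric))
  fm <- do.call(rbind, lapply(strsplit(lines[hdr + nv + seq_len(nf)], "\\s+"),
                              as.numeric))
  surface_mesh(vm[, 1:3, drop = FALSE], fm[, 2:4, drop = FALSE] + 1L)
}
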