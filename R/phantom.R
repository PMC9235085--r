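# Procedural skull-like head phantoms.
#
# The phantom is built from geometric primitives rather than anatomical
# meshes: an ellipsoidal cranial vault shell plus an anterior midfacial
# block with paired cavities standing in for orbits and sinuses and a
# midline nasal corridor. The midfacial block is partitioned into five
# axial bands labelled I (superior, frontal sinus-frontal bone) through V
# (inferior, residual maxilla). All shapes are evaluated on voxel centers
# with analytic membership tests, so symmetry and asymmetry are exactly
# controllable: with asymmetry 0 every structure is mirror-symmetric about
# the midsagittal plane of the voxel grid, and a left-sided asymmetry
# inflates the vault shell outward by a configurable amplitude (mm), which
# makes the expected mirror error analytically checkable.

#' Configuration for a head phantom
#'
#' @param grid integer length-3 `(slices, rows, columns)` voxel grid.
#'   Defaults to 96 x 128 x 128 (desk scale at 1 mm); 64^3 is typical for
#'   unit tests.
#' @param spacing voxel spacing `(dx, dy, dz)` mm.
#' @param shell_mm vault shell thickness in mm (> 0).
#' @param vault_scale multiplier on the vault semi-axes and midfacial block
#'   extents (per-case shape jitter enters here).
#' @param cavity_scale multiplier on all cavity radii (1 = defaults).
#' @param asymmetry_mm amplitude (mm) of the left-sided outward inflation
#'   of the vault shell; 0 gives an exactly mirror-symmetric phantom.
#' @param hu named numeric: `background`, `soft`, `bone` intensity levels
#'   (HU), strictly increasing.
#' @param noise_sd standard deviation of additive Gaussian intensity noise
#'   (HU); 0 (default) gives a clean phantom.
#' @param seed integer seed for the noise field.
#' @return A `head_phantom_config` list.
#' @export
head_phantom_config <- function(grid = c(96, 128, 128),
                                spacing = c(1, 1, 1),
                                shell_mm = 3,
                                vault_scale = 1,
                                cavity_scale = 1,
                                asymmetry_mm = 0,
                                hu = c(background = -1000, soft = 40, bone = 700),
                                noise_sd = 0,
                                seed = 1) {
  grid <- as.integer(grid)
  if (length(grid) != 3L || any(grid < 16L))
    stop("grid too small: need at least 16 voxels per axis to contain all five subunits")
  if (shell_mm <= 0) stop("shell thickness must be > 0")
  if (asymmetry_mm < 0) stop("asymmetry amplitude must be >= 0")
  hu <- hu[c("background", "soft", "bone")]
  if (any(is.na(hu)) || !(hu["bone"] > hu["soft"] && hu["soft"] > hu["background"]))
    stop("need bone HU > soft-tissue HU > background HU")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (vault_scale <= 0) stop("vault_scale must be > 0")
  structure(list(grid = grid, spacing = as.numeric(spacing),
                 shell_mm = shell_mm, vault_scale = vault_scale,
                 cavity_scale = cavity_scale,
                 asymmetry_mm = asymmetry_mm, hu = hu,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "head_phantom_config")
}

# Geometry of one phantom, all in mm. Lx etc. are full grid extents.
.phantom_geometry <- function(config) {
  g <- config$grid; sp <- config$spacing
  Lx <- (g[3] - 1) * sp[1]; Ly <- (g[2] - 1) * sp[2]; Lz <- (g[1] - 1) * sp[3]
  cx <- Lx / 2 # midsagittal plane: x = cx (between voxel centers for even nx)
  vs <- config$vault_scale
  vault <- list(center = c(cx, 0.52 * Ly, 0.66 * Lz),
                semi = vs * c(0.34 * Lx, 0.38 * Ly, 0.30 * Lz))
  block <- list(x = cx + vs * c(-0.24, 0.24) * Lx,
                y = 0.25 * Ly + vs * c(-0.17, 0.17) * Ly,
                z = 0.31 * Lz + vs * c(-0.21, 0.21) * Lz)
  bands <- seq(block$z[1], block$z[2], length.out = 6) # V..I bottom-up
  cs <- config$cavity_scale
  zmid <- function(band) (bands[7 - band - 1] + bands[7 - band]) / 2 # band in 1..5, I=top
  cavities <- list( # spheres: center, radius (soft tissue)
    list(center = c(cx - 0.055 * Lx, 0.24 * Ly, zmid(1)), r = 0.040 * Lx * cs), # frontal sinus L
    list(center = c(cx + 0.055 * Lx, 0.24 * Ly, zmid(1)), r = 0.040 * Lx * cs), # frontal sinus R
    list(center = c(cx - 0.13 * Lx, 0.25 * Ly, zmid(2)), r = 0.055 * Lx * cs),  # orbit L
    list(center = c(cx + 0.13 * Lx, 0.25 * Ly, zmid(2)), r = 0.055 * Lx * cs),  # orbit R
    list(center = c(cx - 0.11 * Lx, 0.25 * Ly, zmid(3)), r = 0.050 * Lx * cs),  # maxillary sinus L
    list(center = c(cx + 0.11 * Lx, 0.25 * Ly, zmid(3)), r = 0.050 * Lx * cs)   # maxillary sinus R
  )
  nasal <- list(x = cx + c(-0.035, 0.035) * Lx,
                y = c(block$y[1], 0.34 * Ly),
                z = c(bands[2], bands[5])) # spans bands II-IV
  landmarks <- rbind(
    glabella = c(cx, block$y[1], bands[6]),
    nasion = c(cx, block$y[1], bands[5]),
    anterior_nasal_spine = c(cx, block$y[1], bands[2]),
    basion = c(cx, 0.60 * Ly, 0.30 * Lz)
  )
  colnames(landmarks) <- c("x", "y", "z")
  list(Lx = Lx, Ly = Ly, Lz = Lz, plane_x = cx, vault = vault, block = block,
       bands = bands, cavities = cavities, nasal = nasal,
       landmarks = landmarks)
}

#' Generate a skull-like head phantom
#'
#' Produces a `volume` (HU intensities), a subunit label map (integer array
#' with labels 0 = none, 1..5 = midfacial subunits I..V), a landmark set on
#' the midsagittal plane, and the analytic geometry the phantom was built
#' from. Fully deterministic given the config (including its seed).
#'
#' @param config a [head_phantom_config()].
#' @return A `head_phantom` list: `volume`, `labels` (integer array, same
#'   shape), `landmarks` (matrix with rows named glabella, nasion,
#'   anterior_nasal_spine, basion; columns x, y, z in mm), `geometry`,
#'   `config`.
#' @export
generate_head_phantom <- function(config = head_phantom_config()) {
  stopifnot(inherits(config, "head_phantom_config"))
  g <- config$grid; sp <- config$spacing
  geo <- .phantom_geometry(config)
  nz <- g[1]; ny <- g[2]; nx <- g[3]
  z <- (seq_len(nz) - 1) * sp[3]
  y <- (seq_len(ny) - 1) * sp[2]
  x <- (seq_len(nx) - 1) * sp[1]
  # full coordinate arrays [slice, row, col]
  Z <- array(rep(z, times = ny * nx), c(nz, ny, nx))
  Y <- array(rep(rep(y, each = nz), times = nx), c(nz, ny, nx))
  X <- array(rep(x, each = nz * ny), c(nz, ny, nx))

  vox <- array(config$hu[["background"]], c(nz, ny, nx))
  labels <- array(0L, c(nz, ny, nx))

  # --- cranial vault shell (with optional left-sided outward inflation) ---
  v <- geo$vault
  # inflation amplitude per voxel: ramps from 0 at the midplane to the full
  # asymmetry amplitude beyond 35% of the lateral semi-axis, left side only
  infl <- config$asymmetry_mm *
    smoothstep(((geo$plane_x - X) / v$semi[1]) / 0.35)
  rho_out <- sqrt(((X - v$center[1]) / (v$semi[1] + infl))^2 +
                  ((Y - v$center[2]) / (v$semi[2] + infl))^2 +
                  ((Z - v$center[3]) / (v$semi[3] + infl))^2)
  si <- pmax(v$semi - config$shell_mm, config$shell_mm)
  rho_in <- sqrt(((X - v$center[1]) / (si[1] + infl))^2 +
                 ((Y - v$center[2]) / (si[2] + infl))^2 +
                 ((Z - v$center[3]) / (si[3] + infl))^2)
  vault_shell <- rho_out <= 1 & rho_in > 1
  vault_interior <- rho_in <= 1
  vox[vault_interior] <- config$hu[["soft"]]
  vox[vault_shell] <- config$hu[["bone"]]

  # --- midfacial block with cavities ---
  b <- geo$block
  in_block <- X >= b$x[1] & X <= b$x[2] & Y >= b$y[1] & Y <= b$y[2] &
    Z >= b$z[1] & Z <= b$z[2]
  vox[in_block] <- config$hu[["bone"]]
  n <- geo$nasal
  in_nasal <- X >= n$x[1] & X <= n$x[2] & Y >= n$y[1] & Y <= n$y[2] &
    Z >= n$z[1] & Z <= n$z[2]
  vox[in_block & in_nasal] <- config$hu[["soft"]]
  for (cv in geo$cavities) {
    in_cav <- (X - cv$center[1])^2 + (Y - cv$center[2])^2 +
      (Z - cv$center[3])^2 <= cv$r^2
    vox[in_block & in_cav] <- config$hu[["soft"]]
  }

  # --- subunit labels: bone voxels of the block, five axial bands ---
  is_bone <- vox >= (config$hu[["soft"]] + config$hu[["bone"]]) / 2
  bands <- geo$bands
  for (lab in 1:5) {
    zlo <- bands[6 - lab]; zhi <- bands[7 - lab] # label 1 = top band
    sel <- in_block & is_bone & Z >= zlo & Z < zhi
    if (lab == 1) sel <- in_block & is_bone & Z >= zlo & Z <= bands[6]
    labels[sel] <- lab
  }

  if (config$noise_sd > 0) {
    noise <- with_seed(config$seed,
                       array(rnorm(length(vox), 0, config$noise_sd), dim(vox)))
    vox <- vox + noise
  }

  structure(list(
    volume = volume(vox, spacing = sp, origin = c(0, 0, 0)),
    labels = labels,
    landmarks = geo$landmarks,
    geometry = geo,
    config = config
  ), class = "head_phantom")
}

#' @export
print.head_phantom <- function(x, ...) {
  d <- dim(x$volume$voxels)
  cat(sprintf("<head_phantom> %d x %d x %d voxels, asymmetry %.2g mm\n",
              d[1], d[2], d[3], x$config$asymmetry_mm))
  tab <- table(factor(x$labels[x$labels > 0], levels = 1:5))
  cat("  subunit voxels (I..V):", paste(tab, collapse = " "), "\n")
  invisible(x)
}

#' Write a head phantom to disk
#'
#' The intensity volume and the subunit label map are written as DICOM
#' series (`volume/`, `labels/`); landmarks, geometry and config go to a
#' `phantom.json` sidecar.
#'
#' @param phantom a `head_phantom`.
#' @param dir output directory.
#' @return Invisibly, `dir`.
#' @export
write_phantom <- function(phantom, dir) {
  stopifnot(inherits(phantom, "head_phantom"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_dicom_series(phantom$volume, file.path(dir, "volume"))
  write_dicom_series(volume(phantom$labels + 0, phantom$volume$spacing,
                            phantom$volume$origin),
                     file.path(dir, "labels"), slope = 1, intercept = 0)
  jsonlite::write_json(list(
    landmarks = as.data.frame(phantom$landmarks),
    landmark_names = rownames(phantom$landmarks),
    plane_x = phantom$geometry$plane_x,
    config = unclass(phantom$config)),
    file.path(dir, "phantom.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Region predicate for the asymmetry-perturbed vault cap
#'
#' Returns a predicate (usable as the `region` argument of
#' [mean_surface_error()] or as a `defect_region`) selecting the lateral
#' vault cap on the perturbed (left, x < midplane) side of a phantom:
#' the zone where the configured asymmetry inflation is at full
#' amplitude, away from the midfacial block. On the vault the inflated
#' shell is offset outward by the full asymmetry amplitude there, which is
#' what makes "mirror error equals asymmetry amplitude" checkable.
#'
#' @param phantom a `head_phantom`.
#' @param lateral_frac minimum lateral offset from the midplane, as a
#'   fraction of the vault x semi-axis (default 0.45, past the end of the
#'   inflation ramp).
#' @return Function mapping an n x 3 coordinate matrix to a logical
#'   vector.
#' @export
asymmetric_region <- function(phantom, lateral_frac = 0.45) {
  geo <- phantom$geometry
  px <- geo$plane_x
  sx <- geo$vault$semi[1]
  ztop <- geo$block$z[2]
  function(v) {
    (px - v[, 1]) / sx > lateral_frac & v[, 3] > ztop + 2
  }
}

#' Generate a cohort of head phantoms with per-case jitter
#'
#' Each case perturbs the vault/block scale and cavity radii by a uniform
#' factor in `1 +- jitter` (seeded; symmetric perturbations, so phantoms
#' stay mirror-symmetric unless `asymmetry_mm > 0`).
#'
#' @param n number of cases (>= 1).
#' @param config base [head_phantom_config()].
#' @param seed integer cohort seed.
#' @param jitter relative scale jitter (0 = identical phantoms).
#' @return List of `head_phantom` objects, named `case001`, ...
#' @export
generate_cohort <- function(n, config = head_phantom_config(), seed = 1,
                            jitter = 0.05) {
  if (!is.numeric(n) || n < 1) stop("'n' must be >= 1")
  n <- as.integer(n)
  draws <- with_seed(seed, matrix(runif(3L * n, -jitter, jitter), ncol = 3))
  out <- vector("list", n)
  for (i in seq_len(n)) {
    cfg <- config
    cfg$vault_scale <- config$vault_scale * (1 + draws[i, 1])
    cfg$cavity_scale <- config$cavity_scale * (1 + draws[i, 2])
    cfg$shell_mm <- config$shell_mm * (1 + draws[i, 3])
    cfg$seed <- config$seed + i
    out[[i]] <- generate_head_phantom(cfg)
  }
  names(out) <- sprintf("case%03d", seq_len(n))
  out
}
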