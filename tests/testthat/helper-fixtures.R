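# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, force(expr), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

test_phantom <- function() {
  fixture("phantom64",
          generate_head_phantom(head_phantom_config(grid = c(64, 64, 64))))
}

test_bone <- function() fixture("bone64", segment_bone(test_phantom()$volume, 300))

test_surface <- function() fixture("surf64", extract_surface(test_bone()))

# one carved defect on the shared phantom
test_defect <- function() {
  fixture("defect64", {
    ph <- test_phantom()
    spec <- sample_defect_spec(ph, 3, c(10, 20), seed = 7)
    c(carve_defect(ph$volume, test_bone(), spec), list(spec = spec))
  })
}

test_pairs <- function() {
  fixture("pairs64", {
    d <- test_defect()
    make_slice_pairs(test_phantom()$volume, d$volume, d$mask, case_id = "fix")
  })
}

# digital ball mask: voxel centers within radius r of the grid center
ball_mask <- function(n, r) {
  ctr <- (n - 1) / 2
  co <- 0:(n - 1)
  Z <- array(rep(co, n * n), c(n, n, n))
  Y <- array(rep(rep(co, each = n), n), c(n, n, n))
  X <- array(rep(co, each = n * n), c(n, n, n))
  ((X - ctr)^2 + (Y - ctr)^2 + (Z - ctr)^2 <= r^2) * 1L
}

# analytic UV-sphere mesh (lat-long triangulation)
uv_sphere <- function(radius, center = c(0, 0, 0), nlat = 48, nlon = 96) {
  lat <- seq(0, pi, length.out = nlat + 1)[2:nlat] # exclude poles
  lon <- seq(0, 2 * pi, length.out = nlon + 1)[1:nlon]
  ring <- function(phi) cbind(radius * sin(phi) * cos(lon),
                              radius * sin(phi) * sin(lon),
                              radius * cos(phi))
  verts <- do.call(rbind, lapply(lat, ring))
  verts <- rbind(verts, c(0, 0, radius), c(0, 0, -radius))
  np <- nrow(verts) - 1L # north pole index (top, z = +r)
  sp <- nrow(verts)
  idx <- function(i, j) (i - 1L) * nlon + ((j - 1L) %% nlon) + 1L
  tris <- list()
  for (i in seq_len(nlat - 2)) {
    for (j in seq_len(nlon)) {
      a <- idx(i, j); b <- idx(i, j + 1); c_ <- idx(i + 1, j); d <- idx(i + 1, j + 1)
      tris[[length(tris) + 1L]] <- c(a, b, d)
      tris[[length(tris) + 1L]] <- c(a, d, c_)
    }
  }
  for (j in seq_len(nlon)) {
    tris[[length(tris) + 1L]] <- c(np, idx(1, j), idx(1, j + 1))
    tris[[length(tris) + 1L]] <- c(sp, idx(nlat - 1, j + 1), idx(nlat - 1, j))
  }
  verts <- sweep(verts, 2, center, "+")
  surface_mesh(verts, do.call(rbind, tris))
}
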