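test_that("cosine similarity identities hold", {
  set.seed(21)
  a <- matrix(sample(0:255, 64, TRUE), 8, 8)
  expect_equal(cosine_similarity(a, a), 1, tolerance = 1e-12)
  # disjoint support
  b <- matrix(0, 8, 8); b[1, 1] <- 10
  c_ <- matrix(0, 8, 8); c_[8, 8] <- 10
  expect_equal(cosine_similarity(b, c_), 0)
  # hand-computed 4-vector case: 20/30
  expect_equal(cosine_similarity(matrix(1:4, 2), matrix(4:1, 2)), 20 / 30,
               tolerance = 1e-12)
  expect_error(cosine_similarity(matrix(0, 2, 2), a[1:2, 1:2]), "all-zero")
  expect_error(cosine_similarity(a, a[1:4, 1:4]), "identical shape")
})

test_that("cosine similarity is scale-invariant and symmetric", {
  set.seed(22)
  a <- matrix(runif(100, 0, 255), 10)
  b <- matrix(runif(100, 0, 255), 10)
  expect_equal(cosine_similarity(a, b), cosine_similarity(b, a),
               tolerance = 1e-14)
  for (s in c(0.001, 3, 1e6))
    expect_equal(cosine_similarity(a * s, b), cosine_similarity(a, b),
                 tolerance = 1e-12)
})

test_that("per-case aggregation averages slices with optional area weights", {
  expect_equal(aggregate_case_similarity(0.7), 0.7)
  expect_equal(aggregate_case_similarity(c(0.9, 1.0)), 0.95)
  expect_equal(aggregate_case_similarity(c(0.9, 1.0), c(1, 3)), 0.975)
  expect_error(aggregate_case_similarity(numeric(0)), "no slice")
})

test_that("mean surface error is zero on self, symmetric, and bounded by translations", {
  m <- uv_sphere(10, nlat = 24, nlon = 48)
  expect_equal(mean_surface_error(m, m), 0)
  m2 <- uv_sphere(12, center = c(1, 1, 0), nlat = 24, nlon = 48)
  expect_equal(mean_surface_error(m, m2), mean_surface_error(m2, m),
               tolerance = 1e-12)
  # error under pure translation never exceeds the translation norm
  d <- c(1.5, -0.5, 1)
  mt <- surface_mesh(m$vertices + matrix(d, nrow(m$vertices), 3, TRUE),
                     m$triangles)
  expect_lte(mean_surface_error(m, mt), sqrt(sum(d^2)))
  # and vanishes after registration
  tf <- register_rigid(m, mt)
  expect_lt(mean_surface_error(apply_transform(tf, m), mt), 1e-6)
})

test_that("concentric analytic spheres recover the 1 mm offset within 3%", {
  m20 <- uv_sphere(20, nlat = 48, nlon = 96)
  m21 <- uv_sphere(21, nlat = 48, nlon = 96)
  expect_equal(mean_surface_error(m20, m21), 1.0, tolerance = 0.03)
})

test_that("one-sided mode and region restriction work", {
  m20 <- uv_sphere(20, nlat = 24, nlon = 48)
  m21 <- uv_sphere(21, nlat = 24, nlon = 48)
  e1 <- mean_surface_error(m20, m21, mode = "one_sided")
  expect_equal(e1, 1.0, tolerance = 0.05)
  upper <- function(v) v[, 3] > 0
  eu <- mean_surface_error(m20, m21, region = upper)
  expect_equal(eu, 1.0, tolerance = 0.05)
  none <- function(v) rep(FALSE, nrow(v))
  expect_error(mean_surface_error(m20, m21, region = none), "empty region")
})

test_that("plane fitting rejects collinear landmarks", {
  pts <- cbind(1:5, 1:5, 1:5)
  expect_error(midfacer:::fit_plane(pts), "collinear")
  pl <- midfacer:::fit_plane(rbind(c(0, 0, 0), c(0, 1, 0), c(0, 0, 1),
                                   c(0, 2, 3)))
  expect_equal(abs(pl$normal), c(1, 0, 0), tolerance = 1e-12)
})

test_that("mirror reference of a symmetric phantom matches the original surface", {
  ph <- test_phantom()
  surf <- test_surface()
  mir <- mirror_reference(surf, ph$landmarks, refine = FALSE)
  expect_lt(mean_surface_error(mir, surf), 0.1)
  mir2 <- mirror_reference(surf, ph$landmarks, refine = TRUE)
  expect_lt(mean_surface_error(mir2, surf), 0.1)
  expect_error(mirror_reference(surf, cbind(1:4, 1:4, 1:4)), "collinear")
})

test_that("evaluate_reconstruction pins the full pipeline with an oracle generator", {
  ph <- test_phantom()
  d <- test_defect()
  t8 <- to_grayscale8(ph$volume)
  oracle <- function(def8, msk, s) t8[s, , ] / 255
  recon <- reconstruct_volume(oracle, d$volume, d$mask)
  ev <- evaluate_reconstruction(ph$volume, recon, d$mask)
  expect_equal(ev$cosine, 1, tolerance = 1e-12)
  expect_lt(ev$mean_error_mm, 1e-9)
  expect_length(ev$per_slice, sum(apply(d$mask, 1, function(m) any(m != 0))))
})
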