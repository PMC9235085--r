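test_that("phantom generation is deterministic and carries all five subunits", {
  cfg <- head_phantom_config(grid = c(48, 48, 48))
  a <- generate_head_phantom(cfg)
  b <- generate_head_phantom(cfg)
  expect_identical(a$volume$voxels, b$volume$voxels)
  expect_identical(a$labels, b$labels)
  tab <- table(factor(a$labels[a$labels > 0], levels = 1:5))
  expect_true(all(tab > 0))
})

test_that("zero-asymmetry phantoms are exactly mirror-symmetric about the landmark plane", {
  ph <- test_phantom()
  # landmark plane: x = (nx-1)/2 voxel units; reflection maps column c to nx+1-c
  pl <- midfacer:::fit_plane(ph$landmarks)
  expect_equal(abs(pl$normal), c(1, 0, 0), tolerance = 1e-12)
  d <- dim(ph$volume$voxels)
  expect_identical(ph$volume$voxels[, , d[3]:1], ph$volume$voxels)
})

test_that("bone fraction and label placement stay in the sanity envelope", {
  ph <- test_phantom()
  frac <- mean(ph$volume$voxels >= 300)
  expect_gt(frac, 0.01)
  expect_lt(frac, 0.50)
  # labels only inside the midfacial block bounding box
  geo <- ph$geometry
  idx <- which(ph$labels > 0, arr.ind = TRUE)
  x <- (idx[, 3] - 1) * ph$config$spacing[1]
  y <- (idx[, 2] - 1) * ph$config$spacing[2]
  z <- (idx[, 1] - 1) * ph$config$spacing[3]
  expect_true(all(x >= geo$block$x[1] & x <= geo$block$x[2]))
  expect_true(all(y >= geo$block$y[1] & y <= geo$block$y[2]))
  expect_true(all(z >= geo$block$z[1] & z <= geo$block$z[2]))
  # labels sit on bone
  expect_true(all(ph$volume$voxels[ph$labels > 0] >= 300))
})

test_that("landmarks recover the configured midsagittal plane", {
  ph <- test_phantom()
  pl <- midfacer:::fit_plane(ph$landmarks)
  px <- ph$geometry$plane_x
  expect_lt(abs(unname(pl$point[1]) - px), 1e-6)
  expect_lt(abs(abs(pl$normal[1]) - 1), 1e-9)
})

test_that("cohorts jitter deterministically", {
  cfg <- head_phantom_config(grid = c(32, 32, 32))
  co0 <- generate_cohort(3, cfg, seed = 4, jitter = 0)
  expect_identical(co0[[1]]$volume$voxels, co0[[2]]$volume$voxels)
  co <- generate_cohort(3, cfg, seed = 4, jitter = 0.08)
  expect_false(identical(co[[1]]$volume$voxels, co[[2]]$volume$voxels))
  expect_false(identical(co[[2]]$volume$voxels, co[[3]]$volume$voxels))
  co2 <- generate_cohort(3, cfg, seed = 4, jitter = 0.08)
  expect_identical(co[[3]]$volume$voxels, co2[[3]]$volume$voxels)
  expect_error(generate_cohort(0, cfg), ">= 1")
})

test_that("degenerate configs are rejected", {
  expect_error(head_phantom_config(grid = c(8, 8, 8)), "too small")
  expect_error(head_phantom_config(shell_mm = 0), "> 0")
  expect_error(head_phantom_config(asymmetry_mm = -1), ">= 0")
  expect_error(head_phantom_config(hu = c(background = 0, soft = -10, bone = 700)))
})
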