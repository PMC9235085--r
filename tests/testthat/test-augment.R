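test_that("identity augmentation returns the pair unchanged", {
  p <- test_pairs()[[1]]
  id <- augment_params(flip_prob = 0, scale_range = c(1, 1),
                       max_rotation_deg = 0, noise_sd = 0)
  a <- augment(p, id, seed = 1)
  expect_identical(a$truth, p$truth)
  expect_identical(a$defect, p$defect)
  expect_identical(a$mask, p$mask)
})

test_that("horizontal flip is applied to all three images and is an involution", {
  p <- test_pairs()[[1]]
  fl <- augment_params(flip_prob = 1, scale_range = c(1, 1),
                       max_rotation_deg = 0, noise_sd = 0)
  a <- augment(p, fl, seed = 1)
  expect_identical(a$truth, p$truth[, ncol(p$truth):1])
  expect_identical(a$mask, p$mask[, ncol(p$mask):1])
  b <- augment(a, fl, seed = 2)
  expect_identical(b$truth, p$truth)
  expect_identical(b$defect, p$defect)
})

test_that("one shared geometric transform hits truth, defect and mask", {
  p <- test_pairs()[[2]]
  pr <- augment_params(flip_prob = 1, scale_range = c(1.15, 1.15),
                       max_rotation_deg = 0, noise_sd = 0)
  # fixed draw: flip = TRUE, scale = 1.15, angle = 0
  a <- augment(p, pr, seed = 3)
  w <- function(img, interp) midfacer:::affine_warp(img, 0, 1.15, TRUE, interp)
  expect_equal(a$truth, w(p$truth, "bilinear"))
  expect_equal(a$defect, w(p$defect, "bilinear"))
  expect_equal(a$mask, w(p$mask, "nearest"))
  expect_true(all(a$mask %in% c(0, 1)))
})

test_that("rotation keeps the mask binary and is seed-deterministic", {
  p <- test_pairs()[[1]]
  pr <- augment_params(flip_prob = 0.5, scale_range = c(0.8, 1.2),
                       max_rotation_deg = 11, noise_sd = 2)
  a1 <- augment(p, pr, seed = 10)
  a2 <- augment(p, pr, seed = 10)
  expect_identical(a1, a2)
  expect_true(all(a1$mask %in% c(0, 1)))
  expect_true(all(a1$truth >= 0 & a1$truth <= 255))
})

test_that("Gaussian noise has the half-normal mean absolute perturbation", {
  img <- matrix(128, 1000, 1000)
  p <- structure(list(truth = img, defect = img, mask = img * 0,
                      case_id = "n", slice_index = 1L), class = "slice_pair")
  pr <- augment_params(flip_prob = 0, scale_range = c(1, 1),
                       max_rotation_deg = 0, noise_sd = 5)
  a <- augment(p, pr, seed = 42)
  m <- mean(abs(a$truth - 128))
  expect_equal(m, 5 * sqrt(2 / pi), tolerance = 0.01)
})

test_that("augmentation parameter validation rejects bad values", {
  expect_error(augment_params(flip_prob = 1.2))
  expect_error(augment_params(scale_range = c(1.2, 0.8)))
  expect_error(augment_params(max_rotation_deg = -1))
  expect_error(augment_params(noise_sd = -1))
})
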