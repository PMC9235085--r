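test_that("generator forward honours shape, range and determinism contracts", {
  g <- build_generator(depth = 18, base_width = 4, resolution = 32, seed = 1)
  x <- matrix(runif(32 * 32, 0, 255), 32, 32)
  o1 <- generator_forward(g, x, z = rep(0.3, 8))
  o2 <- generator_forward(g, x, z = rep(0.3, 8))
  expect_equal(dim(o1), dim(x))
  expect_identical(o1, o2)
  expect_gte(min(o1), 0)
  expect_lte(max(o1), 1)
  expect_error(generator_forward(g, matrix(0, 16, 16)), "resolution")
  expect_error(build_generator(depth = 50), "18, 34, 101")
  expect_error(build_generator(resolution = 30), "multiple of 8")
})

test_that("deeper presets build and preserve shape", {
  for (d in c(34, 101)) {
    g <- build_generator(depth = d, base_width = 2, resolution = 16, seed = 2)
    o <- generator_forward(g, matrix(100, 16, 16))
    expect_equal(dim(o), c(16, 16))
    expect_true(all(is.finite(o)))
  }
})

test_that("discriminator produces a finite squashed score", {
  d <- build_discriminator(base_width = 4, resolution = 32, seed = 1)
  x <- matrix(runif(32 * 32, 0, 255), 32, 32)
  y <- matrix(runif(32 * 32, 0, 255), 32, 32)
  s1 <- discriminator_forward(d, x, y)
  s2 <- discriminator_forward(d, x, y)
  expect_identical(s1, s2)
  expect_true(is.finite(s1$logit))
  expect_gt(s1$prob, 0); expect_lt(s1$prob, 1)
  for (img in list(matrix(0, 32, 32), matrix(255, 32, 32))) {
    s <- discriminator_forward(d, img, img)
    expect_true(is.finite(s$logit))
  }
  expect_error(discriminator_forward(d, matrix(0, 16, 16), y), "resolution")
})

test_that("training config validation rejects degenerate settings", {
  expect_error(gan_config(lr = 0), "> 0")
  expect_error(gan_config(epochs = 0), ">= 1")
  expect_error(gan_config(lambda_adv = 0, lambda_rec = 0), "degenerate")
})

nn_flatten_params_public <- function(fit)
  midfacer:::nn_flatten_params(fit$generator$net)

test_that("YAML training configs round-trip through gan_config_from_yaml", {
  skip_if_not_installed("yaml")
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("epochs: 5", "batch_size: 2", "lr: 0.001", "seed: 7",
               "augment:", "  flip_prob: 0.25", "  noise_sd: 1"), f)
  cfg <- gan_config_from_yaml(f)
  expect_equal(cfg$epochs, 5L)
  expect_equal(cfg$lr, 0.001)
  expect_equal(cfg$augment$flip_prob, 0.25)
  writeLines("nonsense: 1", f)
  expect_error(gan_config_from_yaml(f), "unknown config keys")
})

test_that("a short training run keeps bookkeeping contracts and reproduces", {
  pairs <- test_pairs()[1:6]
  cfg <- gan_config(epochs = 2, batch_size = 2, base_width = 4, seed = 3)
  fit <- train_gan(pairs, cfg)
  expect_s3_class(fit, "gan_fit")
  expect_equal(nrow(fit$history), 2)
  expect_true(all(c("d_loss", "g_loss", "g_adv", "g_l1") %in%
                    names(fit$history)))
  expect_true(all(is.finite(as.matrix(fit$history[-1]))))
  fit2 <- train_gan(pairs, cfg)
  expect_equal(fit$history, fit2$history)
  expect_equal(nn_flatten_params_public(fit), nn_flatten_params_public(fit2))
  expect_error(train_gan(list(), cfg), "empty")
})

test_that("checkpoints round-trip through save_gan/load_gan", {
  pairs <- test_pairs()[1:4]
  fit <- train_gan(pairs, gan_config(epochs = 1, batch_size = 2,
                                     base_width = 4, seed = 5))
  base <- tempfile()
  save_gan(fit, base)
  expect_true(file.exists(paste0(base, ".json")))
  back <- load_gan(base)
  p <- pairs[[1]]
  expect_identical(generator_forward(back$generator, p$defect, NULL, p$mask),
                   generator_forward(fit$generator, p$defect, NULL, p$mask))
  unlink(paste0(base, c(".rds", ".json")))
})

test_that("volume reconstruction composites only inside the mask", {
  d <- test_defect()
  ph <- test_phantom()
  g <- build_generator(depth = 18, base_width = 4, resolution = 64, seed = 9)
  recon <- reconstruct_volume(g, d$volume, d$mask)
  expect_identical(recon$voxels[d$mask == 0], d$volume$voxels[d$mask == 0])
  expect_false(identical(recon$voxels, d$volume$voxels))
  # empty mask -> no-op (idempotence on already-reconstructed volumes)
  empty <- array(0L, dim(d$mask))
  expect_identical(reconstruct_volume(g, recon, empty)$voxels, recon$voxels)
  # oracle passthrough restores the truth inside the mask
  t8 <- to_grayscale8(ph$volume)
  oracle <- function(def8, msk, s) t8[s, , ] / 255
  ro <- reconstruct_volume(oracle, d$volume, d$mask)
  g8 <- to_grayscale8(ro)
  expect_identical(g8[d$mask == 1], t8[d$mask == 1])
})

test_that("predict method dispatches on slice pairs and volumes", {
  d <- test_defect()
  pairs <- test_pairs()[1:4]
  fit <- train_gan(pairs, gan_config(epochs = 1, batch_size = 2,
                                     base_width = 4, seed = 6))
  sl <- predict(fit, pairs[[1]])
  expect_equal(dim(sl), dim(pairs[[1]]$truth))
  expect_identical(sl[pairs[[1]]$mask == 0], pairs[[1]]$defect[pairs[[1]]$mask == 0])
  vol <- predict(fit, d$volume, mask3d = d$mask)
  expect_s3_class(vol, "volume")
})
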