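# Conditional GAN for per-slice defect inpainting.
#
# The generator G(x, z) is a residual-network encoder (configurable depth:
# 18/34 basic blocks, 101 bottleneck blocks) followed by a nearest-neighbour
# upsampling decoder; it receives the defect image x, the defect mask and a
# broadcast noise channel built from z, and emits a same-size image in
# [0, 1] through a sigmoid. The discriminator D(x, y) scores the
# conditional pair (defect image, candidate) through 3 convolution layers
# (kernel 3, batch norm, leaky ReLU) and a scalar head. Training follows
# the pix2pix convention: non-saturating adversarial loss plus a weighted
# L1 reconstruction term (default 1:100).

RESNET_BLOCKS <- list(`18` = c(2, 2, 2, 2), `34` = c(3, 4, 6, 3),
                      `101` = c(3, 4, 23, 3))

.basic_block <- function(in_ch, out_ch, stride) {
  main <- nn_seq(list(
    nn_conv(in_ch, out_ch, 3, stride), nn_bn(out_ch), nn_lrelu(),
    nn_conv(out_ch, out_ch, 3, 1), nn_bn(out_ch)))
  proj <- if (stride != 1 || in_ch != out_ch)
    nn_seq(list(nn_conv(in_ch, out_ch, 1, stride, pad = 0), nn_bn(out_ch)))
  nn_res(main, proj)
}

.bottleneck_block <- function(in_ch, mid_ch, stride) {
  out_ch <- mid_ch * 4
  main <- nn_seq(list(
    nn_conv(in_ch, mid_ch, 1, 1, pad = 0), nn_bn(mid_ch), nn_lrelu(),
    nn_conv(mid_ch, mid_ch, 3, stride), nn_bn(mid_ch), nn_lrelu(),
    nn_conv(mid_ch, out_ch, 1, 1, pad = 0), nn_bn(out_ch)))
  proj <- if (stride != 1 || in_ch != out_ch)
    nn_seq(list(nn_conv(in_ch, out_ch, 1, stride, pad = 0), nn_bn(out_ch)))
  nn_res(main, proj)
}

#' Build the inpainting generator
#'
#' @param depth residual backbone depth preset: 18, 34 (basic blocks) or
#'   101 (bottleneck blocks). Tests and desk-scale runs use 18; the
#'   101-layer preset mirrors the full-scale configuration.
#' @param base_width channels of the first stage (doubling per stage).
#' @param resolution input/output image side (pixels); the encoder
#'   downsamples by 8, so `resolution` must be a multiple of 8.
#' @param nz dimension of the noise input z.
#' @param seed seed for weight initialization.
#' @return A `generator_model`.
#' @export
build_generator <- function(depth = 18, base_width = 8, resolution = 64,
                            nz = 8, seed = 1) {
  depth <- as.character(depth)
  if (!depth %in% names(RESNET_BLOCKS))
    stop("depth must be one of 18, 34, 101")
  if (resolution %% 8 != 0) stop("resolution must be a multiple of 8")
  blocks <- RESNET_BLOCKS[[depth]]
  bottleneck <- depth == "101"
  widths <- base_width * c(1, 2, 4, 8)
  net <- with_seed(seed, {
    layers <- list(nn_conv(3, widths[1], 3, 1), nn_bn(widths[1]), nn_lrelu())
    in_ch <- widths[1]
    for (s in 1:4) {
      stride <- if (s == 1) 1 else 2
      for (bi in seq_len(blocks[s])) {
        st <- if (bi == 1) stride else 1
        if (bottleneck) {
          layers <- c(layers, list(.bottleneck_block(in_ch, widths[s], st)))
          in_ch <- widths[s] * 4
        } else {
          layers <- c(layers, list(.basic_block(in_ch, widths[s], st)))
          in_ch <- widths[s]
        }
      }
    }
    for (s in 3:1) { # decoder: x8 -> x1
      layers <- c(layers, list(nn_upsample(),
                               nn_conv(in_ch, widths[s], 3, 1),
                               nn_bn(widths[s]), nn_lrelu()))
      in_ch <- widths[s]
    }
    layers <- c(layers, list(nn_conv(in_ch, 1, 3, 1), nn_sigmoid()))
    nn_seq(layers)
  })
  structure(list(net = net,
                 cfg = list(depth = as.integer(depth),
                            base_width = base_width,
                            resolution = as.integer(resolution),
                            nz = as.integer(nz), seed = seed)),
            class = "generator_model")
}

#' Build the conditional discriminator
#'
#' 3 convolution layers (kernel size 3) with batch normalization and leaky
#' ReLU, followed by a global-average-pool scalar head; input is the
#' 2-channel conditional pair (defect image, candidate image).
#'
#' @param base_width channels of the first convolution.
#' @param resolution input image side (pixels).
#' @param seed seed for weight initialization.
#' @return A `discriminator_model`.
#' @export
build_discriminator <- function(base_width = 8, resolution = 64, seed = 1) {
  w <- base_width
  net <- with_seed(seed, nn_seq(list(
    nn_conv(2, w, 3, 1), nn_bn(w), nn_lrelu(),
    nn_conv(w, 2 * w, 3, 2), nn_bn(2 * w), nn_lrelu(),
    nn_conv(2 * w, 4 * w, 3, 2), nn_bn(4 * w), nn_lrelu(),
    nn_gap_dense(4 * w))))
  structure(list(net = net,
                 cfg = list(base_width = base_width,
                            resolution = as.integer(resolution),
                            seed = seed)),
            class = "discriminator_model")
}

# z (length nz, or NULL for the deterministic z = 0) -> one H x W noise
# channel, tiled.
.noise_channel <- function(z, h, w, nz) {
  if (is.null(z)) return(matrix(0, h, w))
  matrix(rep_len(as.numeric(z), h * w), h, w)
}

# assemble the [H, W, 3, N] generator input from lists of matrices
.gen_input <- function(defects, masks, zs, res) {
  n <- length(defects)
  x <- array(0, c(res, res, 3, n))
  for (i in seq_len(n)) {
    x[, , 1, i] <- defects[[i]] / 255
    x[, , 2, i] <- masks[[i]]
    x[, , 3, i] <- zs[[i]]
  }
  x
}

#' Generator forward pass
#'
#' @param model a `generator_model`.
#' @param x defect image: numeric matrix of 8-bit values (0..255) whose
#'   side equals the model resolution.
#' @param z noise vector (length `nz`), or NULL for the deterministic
#'   z = 0 used at reconstruction time.
#' @param mask optional binary defect mask (same shape as `x`; zeros if
#'   omitted).
#' @return Numeric matrix, same shape as `x`, values in \[0, 1\].
#' @export
generator_forward <- function(model, x, z = NULL, mask = NULL) {
  stopifnot(inherits(model, "generator_model"))
  res <- model$cfg$resolution
  if (!is.matrix(x) || nrow(x) != res || ncol(x) != res)
    stop(sprintf("input resolution %dx%d does not match model resolution %d",
                 NROW(x), NCOL(x), res))
  if (is.null(mask)) mask <- matrix(0, res, res)
  if (!identical(dim(mask), dim(x))) stop("mask shape must match x")
  zc <- .noise_channel(z, res, res, model$cfg$nz)
  inp <- .gen_input(list(x), list(mask), list(zc), res)
  out <- nn_forward(model$net, inp, training = FALSE)$y
  matrix(out[, , 1, 1], res, res)
}

#' Discriminator forward pass
#'
#' Scores the conditional pair (defect image `x`, candidate `y`).
#'
#' @param model a `discriminator_model`.
#' @param x defect image, 8-bit values (0..255).
#' @param y candidate image, 8-bit values (0..255).
#' @return List with `logit` (finite scalar) and `prob` (= plogis(logit),
#'   interpretable as probability-of-real in (0, 1)).
#' @export
discriminator_forward <- function(model, x, y) {
  stopifnot(inherits(model, "discriminator_model"))
  res <- model$cfg$resolution
  if (!all(dim(x) == c(res, res)) || !all(dim(y) == c(res, res)))
    stop("input resolution does not match model resolution")
  inp <- array(0, c(res, res, 2, 1))
  inp[, , 1, 1] <- x / 255
  inp[, , 2, 1] <- y / 255
  logit <- as.numeric(nn_forward(model$net, inp, training = FALSE)$y)
  list(logit = logit, prob = stats::plogis(logit))
}

#' Training configuration for the inpainting GAN
#'
#' @param epochs number of epochs (>= 1).
#' @param batch_size minibatch size (>= 1).
#' @param lr Adam learning rate (default 0.002, the standard initial rate
#'   for this architecture family).
#' @param beta1,beta2 Adam moment decays (0.5/0.999, the usual adversarial
#'   setting).
#' @param lambda_adv,lambda_rec adversarial and L1 reconstruction loss
#'   weights (default 1 and 100, the pix2pix convention); non-negative and
#'   not both zero.
#' @param depth,base_width,nz generator architecture, see
#'   [build_generator()].
#' @param augment an [augment_params()], or NULL to disable augmentation.
#' @param seed master seed for weight init, shuffling, z draws and
#'   augmentation.
#' @return A `gan_config`.
#' @export
gan_config <- function(epochs = 30, batch_size = 4, lr = 0.002,
                       beta1 = 0.5, beta2 = 0.999,
                       lambda_adv = 1, lambda_rec = 100,
                       depth = 18, base_width = 8, nz = 8,
                       augment = NULL, seed = 1) {
  if (lr <= 0) stop("learning rate must be > 0")
  if (epochs < 1) stop("epochs must be >= 1")
  if (batch_size < 1) stop("batch_size must be >= 1")
  if (lambda_adv < 0 || lambda_rec < 0) stop("loss weights must be >= 0")
  if (lambda_adv == 0 && lambda_rec == 0)
    stop("degenerate config: adversarial and reconstruction weights are both zero")
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 lr = lr, beta1 = beta1, beta2 = beta2,
                 lambda_adv = lambda_adv, lambda_rec = lambda_rec,
                 depth = depth, base_width = base_width, nz = as.integer(nz),
                 augment = augment, seed = as.integer(seed)),
            class = "gan_config")
}

#' Read a training configuration from a YAML file
#'
#' Top-level keys map to [gan_config()] arguments; an `augment` block maps
#' to [augment_params()]. Unknown keys are rejected.
#'
#' @param path YAML file path.
#' @return A `gan_config`.
#' @export
gan_config_from_yaml <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required to read YAML configs")
  y <- yaml::read_yaml(path)
  if (!is.null(y$augment)) y$augment <- do.call(augment_params, y$augment)
  known <- names(formals(gan_config))
  bad <- setdiff(names(y), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  do.call(gan_config, y)
}

softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))

#' Train the inpainting GAN
#'
#' Alternating discriminator/generator updates with Adam. The
#' discriminator maximizes its score separation between conditional pairs
#' (x, truth) and (x, G(x, z)); the generator minimizes the non-saturating
#' adversarial loss plus `lambda_rec` times the mean absolute error to the
#' truth slice. Seeded end to end, so a rerun with the same inputs and
#' config reproduces the loss history on the same platform.
#'
#' @param pairs non-empty list of `slice_pair`s with square images of one
#'   common resolution (multiple of 8).
#' @param config a [gan_config()].
#' @return A `gan_fit`: list with `generator`, `discriminator`, `history`
#'   (data.frame: epoch, d_loss, g_loss, g_adv, g_l1), `config`. Has
#'   `print()`, `plot()` and `predict()` methods.
#' @export
train_gan <- function(pairs, config = gan_config()) {
  if (length(pairs) == 0) stop("empty training set")
  stopifnot(inherits(config, "gan_config"))
  res <- nrow(pairs[[1]]$truth)
  for (p in pairs)
    if (!all(c(dim(p$truth), dim(p$defect), dim(p$mask)) == res))
      stop("all pairs must share one square resolution")

  gen <- build_generator(config$depth, config$base_width, res, config$nz,
                         seed = config$seed)
  dis <- build_discriminator(config$base_width, res, seed = config$seed + 1)
  opt_g <- adam_init(gen$net)
  opt_d <- adam_init(dis$net)
  n <- length(pairs)
  hist <- data.frame(epoch = integer(0), d_loss = numeric(0),
                     g_loss = numeric(0), g_adv = numeric(0),
                     g_l1 = numeric(0))
  t_g <- 0L; t_d <- 0L

  with_seed(config$seed + 2, {
    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(n, n)
      ep <- c(d_loss = 0, g_loss = 0, g_adv = 0, g_l1 = 0)
      nb <- 0L
      for (start in seq(1, n, by = config$batch_size)) {
        idx <- ord[start:min(start + config$batch_size - 1L, n)]
        batch <- pairs[idx]
        if (!is.null(config$augment))
          batch <- lapply(batch, augment, params = config$augment)
        bs <- length(batch)
        zs <- lapply(seq_len(bs), function(i)
          .noise_channel(rnorm(config$nz), res, res, config$nz))
        gin <- .gen_input(lapply(batch, `[[`, "defect"),
                          lapply(batch, `[[`, "mask"), zs, res)
        truth <- array(0, c(res, res, 1, bs))
        for (i in seq_len(bs)) truth[, , 1, i] <- batch[[i]]$truth / 255

        gfwd <- nn_forward(gen$net, gin, training = TRUE)
        gen$net <- nn_update_state(gen$net, gfwd$state)
        fake <- gfwd$y

        din_real <- array(0, c(res, res, 2, bs))
        din_fake <- din_real
        din_real[, , 1, ] <- gin[, , 1, ]; din_real[, , 2, ] <- truth[, , 1, ]
        din_fake[, , 1, ] <- gin[, , 1, ]; din_fake[, , 2, ] <- fake[, , 1, ]

        # --- discriminator update (fake detached) ---
        fr <- nn_forward(dis$net, din_real, training = TRUE)
        dis$net <- nn_update_state(dis$net, fr$state)
        ff <- nn_forward(dis$net, din_fake, training = TRUE)
        dis$net <- nn_update_state(dis$net, ff$state)
        l_real <- fr$y; l_fake <- ff$y
        d_loss <- mean(softplus(-l_real)) + mean(softplus(l_fake))
        if (!is.finite(d_loss))
          stop(sprintf("non-finite discriminator loss at epoch %d", epoch))
        g1 <- nn_backward(dis$net, fr$cache, -stats::plogis(-l_real) / bs)$grads
        g2 <- nn_backward(dis$net, ff$cache, stats::plogis(l_fake) / bs)$grads
        t_d <- t_d + 1L
        sd_ <- adam_step(dis$net, grads_add(g1, g2), opt_d, config$lr,
                         config$beta1, config$beta2, t = t_d)
        dis$net <- sd_$node; opt_d <- sd_$state

        # --- generator update (through the updated discriminator) ---
        ff2 <- nn_forward(dis$net, din_fake, training = TRUE)
        dis$net <- nn_update_state(dis$net, ff2$state)
        l_fake2 <- ff2$y
        g_adv <- mean(softplus(-l_fake2))
        l1 <- mean(abs(fake - truth))
        g_loss <- config$lambda_adv * g_adv + config$lambda_rec * l1
        if (!is.finite(g_loss))
          stop(sprintf("non-finite generator loss at epoch %d", epoch))
        dfake <- array(0, dim(fake))
        if (config$lambda_adv > 0) {
          dd <- nn_backward(dis$net, ff2$cache,
                            -config$lambda_adv * stats::plogis(-l_fake2) / bs)
          dfake <- dfake + dd$dx[, , 2, , drop = FALSE]
        }
        dfake <- dfake +
          config$lambda_rec * sign(fake - truth) / length(fake)
        gg <- nn_backward(gen$net, gfwd$cache, dfake)$grads
        t_g <- t_g + 1L
        sg <- adam_step(gen$net, gg, opt_g, config$lr,
                        config$beta1, config$beta2, t = t_g)
        gen$net <- sg$node; opt_g <- sg$state

        ep <- ep + c(d_loss, g_loss, g_adv, l1)
        nb <- nb + 1L
      }
      ep <- ep / nb
      hist <- rbind(hist, data.frame(epoch = epoch, d_loss = ep[1],
                                     g_loss = ep[2], g_adv = ep[3],
                                     g_l1 = ep[4]))
    }
  })
  rownames(hist) <- NULL
  structure(list(generator = gen, discriminator = dis, history = hist,
                 config = config),
            class = "gan_fit")
}

#' @export
print.gan_fit <- function(x, ...) {
  h <- x$history
  cat(sprintf(
    "<gan_fit> depth-%d generator, %d epochs\n", x$generator$cfg$depth,
    nrow(h)))
  cat(sprintf("  final losses: D %.4f, G %.4f (adv %.4f, L1 %.4f)\n",
              h$d_loss[nrow(h)], h$g_loss[nrow(h)], h$g_adv[nrow(h)],
              h$g_l1[nrow(h)]))
  invisible(x)
}

#' @export
plot.gan_fit <- function(x, ...) {
  h <- x$history
  graphics::matplot(h$epoch, cbind(h$d_loss, h$g_l1), type = "l", lty = 1,
                    xlab = "epoch", ylab = "loss",
                    main = "GAN training losses", ...)
  graphics::legend("topright", c("discriminator", "generator L1"),
                   col = 1:2, lty = 1, bty = "n")
  invisible(x)
}

#' Predict method for a trained GAN
#'
#' Inpaints either a single `slice_pair` (returns the reconstructed 8-bit
#' slice) or a defect [volume()] plus 3D mask (returns the reconstructed
#' volume via [reconstruct_volume()]).
#'
#' @param object a `gan_fit`.
#' @param newdata a `slice_pair` or a [volume()].
#' @param mask3d 3D mask (required when `newdata` is a volume).
#' @param window grayscale window for volume reconstruction.
#' @param z noise vector (NULL = deterministic z = 0).
#' @param ... unused.
#' @return Matrix (8-bit slice) or [volume()].
#' @export
predict.gan_fit <- function(object, newdata, mask3d = NULL,
                            window = c(-1000, 2000), z = NULL, ...) {
  if (inherits(newdata, "slice_pair")) {
    out <- generator_forward(object$generator, newdata$defect, z,
                             newdata$mask)
    recon <- newdata$defect
    recon[newdata$mask == 1] <- round_half_up(255 * out[newdata$mask == 1])
    return(recon)
  }
  if (is_volume(newdata)) {
    if (is.null(mask3d)) stop("mask3d is required for volume reconstruction")
    return(reconstruct_volume(object$generator, newdata, mask3d, window,
                              z = z))
  }
  stop("newdata must be a slice_pair or a volume")
}

#' Reconstruct a defect volume slice by slice
#'
#' Runs the generator on every axial slice intersecting the defect mask
#' and composites the generator output back into the volume inside the
#' mask only: voxels outside the mask are returned bit-identical.
#' Generator outputs in \[0, 1\] are mapped back to HU through the
#' grayscale window. Slices are resized to the generator resolution and
#' back (bilinear; nearest-neighbour for the mask) when they differ.
#'
#' @param gen a `generator_model`, or a function
#'   `(defect8, mask, slice_index) -> matrix in [0, 1]` (e.g. an oracle
#'   passthrough for pipeline checks).
#' @param defect a [volume()] containing the defect.
#' @param mask3d 3D binary array of carved voxels.
#' @param window grayscale window used for the 8-bit conversion in both
#'   directions.
#' @param z noise vector, or NULL for deterministic z = 0.
#' @param zseed if not NULL, draw z ~ N(0, 1) per slice under this seed.
#' @return The reconstructed [volume()].
#' @export
reconstruct_volume <- function(gen, defect, mask3d,
                               window = c(-1000, 2000), z = NULL,
                               zseed = NULL) {
  stopifnot(is_volume(defect))
  if (!identical(dim(defect$voxels), dim(mask3d)))
    stop("volume and mask shapes differ")
  d8 <- to_grayscale8(defect, window)
  out <- defect$voxels
  d <- dim(out)
  slices <- which(apply(mask3d, 1, function(m) any(m != 0)))
  is_model <- inherits(gen, "generator_model")
  nz <- if (is_model) gen$cfg$nz else 8L
  zdraw <- if (!is.null(zseed))
    with_seed(zseed, lapply(slices, function(s) rnorm(nz)))
  for (k in seq_along(slices)) {
    s <- slices[k]
    def_sl <- matrix(as.numeric(d8[s, , ]), d[2], d[3])
    msk_sl <- matrix(as.numeric(mask3d[s, , ] != 0), d[2], d[3])
    zk <- if (!is.null(zseed)) zdraw[[k]] else z
    if (is_model) {
      res <- gen$cfg$resolution
      din <- if (all(dim(def_sl) == res)) def_sl else
        round(resize_bilinear(def_sl, res, res))
      min_ <- if (all(dim(msk_sl) == res)) msk_sl else
        resize_nearest(msk_sl, res, res)
      o <- generator_forward(gen, din, zk, min_)
      if (!all(dim(def_sl) == res))
        o <- resize_bilinear(o, d[2], d[3])
    } else {
      o <- gen(def_sl, msk_sl, s)
    }
    hu <- gray8_to_hu(255 * o, window)
    sl <- out[s, , ]
    sel <- msk_sl == 1
    sl[sel] <- hu[sel]
    out[s, , ] <- sl
  }
  volume(out, defect$spacing, defect$origin)
}

#' Masked-region reconstruction error of a generator
#'
#' Mean absolute 8-bit error between the generator output and the truth
#' slice, restricted to the defect mask, averaged over the supplied pairs
#' (with deterministic z = 0). The natural figure of merit for comparing
#' a trained generator against its random-weight initialization.
#'
#' @param gen a `generator_model`.
#' @param pairs list of `slice_pair`s.
#' @return Scalar mean absolute error in 8-bit intensity units.
#' @export
masked_reconstruction_error <- function(gen, pairs) {
  errs <- vapply(pairs, function(p) {
    o <- generator_forward(gen, p$defect, NULL, p$mask)
    sel <- p$mask == 1
    if (!any(sel)) return(NA_real_)
    mean(abs(255 * o[sel] - p$truth[sel]))
  }, numeric(1))
  mean(errs, na.rm = TRUE)
}

#' Save / load a GAN checkpoint
#'
#' Weights go to an RDS file (the R ecosystem's standard serialized-object
#' format) next to a JSON architecture descriptor, so a checkpoint is
#' self-describing.
#'
#' @param fit a `gan_fit`.
#' @param path basename (without extension); writes `<path>.rds` and
#'   `<path>.json`.
#' @return Invisibly, `path`.
#' @export
save_gan <- function(fit, path) {
  stopifnot(inherits(fit, "gan_fit"))
  jsonlite::write_json(list(
    generator = fit$generator$cfg, discriminator = fit$discriminator$cfg,
    config = unclass(fit$config)[setdiff(names(fit$config), "augment")]),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  saveRDS(fit, paste0(path, ".rds"))
  invisible(path)
}

#' @rdname save_gan
#' @export
load_gan <- function(path) {
  readRDS(paste0(path, ".rds"))
}
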