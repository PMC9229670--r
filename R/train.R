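## Adversarial training.
##
## Each training step performs one gradient update of the discriminator
## (real pairs labelled real, generated pairs labelled fake, generator
## frozen) followed by one update of the generator (through the frozen
## discriminator, plus the L1 term). The generator uses Adam, the
## discriminator RMSProp with momentum, both at the same learning rate, with
## an optional per-epoch exponential learning-rate schedule. Only the
## generator is needed for inference; the discriminator exists to shape the
## generator's training signal.

#' Training settings
#'
#' @param lambda_l1 weight of the generator's L1 term (75: the 75-to-1 split
#'   in favour of L1 over the adversarial term).
#' @param lr shared initial learning rate for both optimizers.
#' @param adam_beta1,adam_beta2 Adam moment decays for the generator.
#' @param rmsprop_rho,rmsprop_momentum RMSProp decay and momentum for the
#'   discriminator.
#' @param d_pace_factor multiplier on the discriminator objective (0.5 halves
#'   its optimization pace relative to the generator).
#' @param batch_size slices per gradient step.
#' @param epochs maximum training epochs.
#' @param lr_schedule_decay per-epoch exponential learning-rate decay factor;
#'   set `use_lr_schedule = FALSE` to keep the rate constant.
#' @param use_lr_schedule apply the schedule.
#' @param patience early-stop patience in epochs on validation Dice
#'   (`Inf` disables early stopping).
#' @param adversarial train with the discriminator; `FALSE` gives the
#'   supervised concatenated-U-Nets baseline (L1 objective only).
#' @param seed seed for shuffling, augmentation draws and dropout.
#' @return a `train_config` list.
#' @export
train_config <- function(lambda_l1 = 75, lr = 2e-4, adam_beta1 = 0.9,
                         adam_beta2 = 0.999, rmsprop_rho = 0.9,
                         rmsprop_momentum = 0.9, d_pace_factor = 0.5,
                         batch_size = 10L, epochs = 100L,
                         lr_schedule_decay = 0.96, use_lr_schedule = TRUE,
                         patience = Inf, adversarial = TRUE, seed = 42L) {
  stopifnot(lambda_l1 >= 0, lr >= 0, batch_size >= 1L, epochs >= 1L,
            d_pace_factor > 0, d_pace_factor <= 1)
  structure(list(lambda_l1 = lambda_l1, lr = lr, adam_beta1 = adam_beta1,
                 adam_beta2 = adam_beta2, rmsprop_rho = rmsprop_rho,
                 rmsprop_momentum = rmsprop_momentum,
                 d_pace_factor = d_pace_factor,
                 batch_size = as.integer(batch_size), epochs = as.integer(epochs),
                 lr_schedule_decay = lr_schedule_decay,
                 use_lr_schedule = isTRUE(use_lr_schedule), patience = patience,
                 adversarial = isTRUE(adversarial), seed = as.integer(seed)),
            class = "train_config")
}

concat_channels <- function(a, b) {
  da <- dim(a); db <- dim(b)
  array(c(a, b), dim = c(da[1], da[2], da[3] + db[3]))
}

as_chw1 <- function(m) {
  if (is.matrix(m)) array(m, dim = c(dim(m), 1L)) else m
}

#' One adversarial training step on a batch of slice/mask pairs
#'
#' @param batch list of `list(image, mask)` matrices in the network range.
#' @param state training state as produced by [init_train_state()].
#' @param cfg a [train_config()].
#' @param lr learning rate for this step (defaults to `cfg$lr`).
#' @param update which sub-steps to run: `"both"` (the standard alternating
#'   step: one discriminator update followed by one generator update),
#'   `"d"` or `"g"` alone. During the generator sub-step the discriminator
#'   weights are never written, and vice versa.
#' @return the updated state, with the step's losses appended to
#'   `state$step_log`.
#' @export
train_step <- function(batch, state, cfg = train_config(), lr = cfg$lr,
                       update = c("both", "d", "g")) {
  update <- match.arg(update)
  B <- length(batch)
  gen <- state$generator; disc <- state$discriminator
  d_loss_acc <- 0; g_adv_acc <- 0; g_l1_acc <- 0

  ## --- discriminator update (generator frozen) ---
  if (cfg$adversarial && update != "g") {
    dgrads <- NULL
    for (s in batch) {
      x <- as_chw1(s$image); y <- as_chw1(s$mask)
      fake <- generator_forward(gen, x, training = TRUE, keep_cols = FALSE)$y
      fr <- discriminator_forward(disc, concat_channels(x, y), training = TRUE)
      ff <- discriminator_forward(disc, concat_channels(x, fake), training = TRUE)
      npix <- length(fr$prob)
      scale <- cfg$d_pace_factor * 0.5 / (npix * B)
      br <- discriminator_backward(disc, (fr$prob - 1) * scale, fr$cache)
      bf <- discriminator_backward(disc, ff$prob * scale, ff$cache)
      g <- tree_add(br$grads, bf$grads)
      dgrads <- if (is.null(dgrads)) g else tree_add(dgrads, g)
      d_loss_acc <- d_loss_acc +
        discriminator_loss(fr$prob, ff$prob, cfg$d_pace_factor) / B
    }
    if (!all(is.finite(unlist(lapply(dgrads, function(x) tree_sum(x, function(a) sum(!is.finite(a))))))) ||
        !is.finite(d_loss_acc)) {
      stop("non-finite discriminator loss or gradient", call. = FALSE)
    }
    upd <- rmsprop_step(disc$params, dgrads, state$d_opt, lr,
                        cfg$rmsprop_rho, cfg$rmsprop_momentum)
    disc$params <- upd$params
    state$d_opt <- upd$state
  }

  ## --- generator update (discriminator frozen) ---
  if (update == "d") {
    state$generator <- gen
    state$discriminator <- disc
    state$step_log <- rbind(state$step_log,
                            data.frame(g_total = NA_real_, g_adv = NA_real_,
                                       g_l1 = NA_real_, d_loss = d_loss_acc))
    return(state)
  }
  ggrads <- NULL
  for (s in batch) {
    x <- as_chw1(s$image); y <- as_chw1(s$mask)
    gf <- generator_forward(gen, x, training = TRUE, keep_cols = TRUE)
    npix_img <- length(gf$y)
    dl1 <- sign(gf$y - y) / npix_img
    if (cfg$adversarial) {
      df <- discriminator_forward(disc, concat_channels(x, gf$y), training = TRUE)
      npix <- length(df$prob)
      db <- discriminator_backward(disc, (df$prob - 1) / (npix * B), df$cache)
      dfake <- db$dx[, , dim(x)[3] + seq_len(dim(gf$y)[3]), drop = FALSE]
      dy <- dfake + cfg$lambda_l1 * dl1 / B
      g_adv_acc <- g_adv_acc + bce_mean(df$prob, 1) / B
    } else {
      dy <- cfg$lambda_l1 * dl1 / B
    }
    g_l1_acc <- g_l1_acc + l1_loss(gf$y, y) / B
    gb <- generator_backward(gen, dy, gf$cache)
    ggrads <- if (is.null(ggrads)) gb$grads else tree_add(ggrads, gb$grads)
  }
  if (!is.finite(g_l1_acc) || !is.finite(g_adv_acc)) {
    stop("non-finite generator loss", call. = FALSE)
  }
  upd <- adam_step(gen$params, ggrads, state$g_opt, lr,
                   cfg$adam_beta1, cfg$adam_beta2)
  gen$params <- upd$params
  state$g_opt <- upd$state

  state$generator <- gen
  state$discriminator <- disc
  state$step_log <- rbind(state$step_log,
                          data.frame(g_total = g_adv_acc + cfg$lambda_l1 * g_l1_acc,
                                     g_adv = g_adv_acc, g_l1 = g_l1_acc,
                                     d_loss = d_loss_acc))
  state
}

#' Initialise the adversarial training state
#'
#' @param generator,discriminator `network_handle`s (built if missing).
#' @param gen_cfg,disc_cfg configs used when building.
#' @return a `train_state` list with optimizer state and empty history.
#' @export
init_train_state <- function(generator = NULL, discriminator = NULL,
                             gen_cfg = generator_config(),
                             disc_cfg = discriminator_config()) {
  if (is.null(generator)) generator <- build_generator(gen_cfg)
  if (is.null(discriminator)) discriminator <- build_discriminator(disc_cfg)
  list(generator = generator, discriminator = discriminator,
       g_opt = adam_init(generator$params),
       d_opt = rmsprop_init(discriminator$params),
       epoch = 0L, step_log = NULL, history = NULL)
}

# Flatten preprocessed volumes into a list of slice/mask matrix pairs.
volumes_to_slice_pairs <- function(xs, ys) {
  pairs <- list()
  for (v in seq_along(xs)) {
    for (s in seq_len(dim(xs[[v]])[3])) {
      pairs[[length(pairs) + 1L]] <- list(image = xs[[v]][, , s],
                                          mask = ys[[v]][, , s])
    }
  }
  pairs
}

pooled_val_dice <- function(gen, val_x, val_y) {
  tp <- fp <- fn <- 0
  for (v in seq_along(val_x)) {
    for (s in seq_len(dim(val_x[[v]])[3])) {
      pred <- generator_forward(gen, as_chw1(val_x[[v]][, , s]),
                                training = FALSE, keep_cols = FALSE)$y
      pb <- pred[, , 1] > 0
      tb <- val_y[[v]][, , s] > 0
      tp <- tp + sum(pb & tb)
      fp <- fp + sum(pb & !tb)
      fn <- fn + sum(!pb & tb)
    }
  }
  if (2 * tp + fp + fn == 0) return(NA_real_)
  2 * tp / (2 * tp + fp + fn)
}

#' Train the conditional GAN on volumes
#'
#' Volumes are preprocessed (ROI masking, resize, normalization), training
#' slices are augmented on the fly each epoch, and validation Dice is
#' evaluated after every epoch on held-out volumes (which are never
#' augmented). The trained generator is the product; the discriminator is
#' returned for completeness but is not needed for inference.
#'
#' @param train_volumes,val_volumes lists of `list(image, mask)` pairs of
#'   [volume_stack()]s (or 3D arrays); images on the raw 0-255 scale, masks
#'   strictly 0/1. The two sets must be disjoint at the volume level.
#' @param gen_cfg,disc_cfg,cfg,pre_cfg,aug_cfg module configurations.
#' @param verbose print one line per epoch.
#' @return `list(generator, discriminator, history, initial_val_dice)`;
#'   `history` has one row per epoch: epoch, g_total, g_adv, g_l1, d_loss,
#'   val_dice.
#' @export
fit <- function(train_volumes, val_volumes, gen_cfg = generator_config(),
                disc_cfg = discriminator_config(), cfg = train_config(),
                pre_cfg = preprocess_config(), aug_cfg = augment_config(),
                verbose = FALSE) {
  if (!length(train_volumes)) stop("empty training set", call. = FALSE)
  set.seed(cfg$seed)
  pre <- function(v) preprocess_volume(unclass(v$image), pre_cfg, is_mask = FALSE)
  prm <- function(v) preprocess_volume(unclass(v$mask), pre_cfg, is_mask = TRUE)
  tx <- lapply(train_volumes, pre); ty <- lapply(train_volumes, prm)
  vx <- lapply(val_volumes, pre)
  vy <- lapply(val_volumes, function(v) {
    d <- dim(v$mask)
    out <- array(0, c(pre_cfg$target_size, pre_cfg$target_size, d[3]))
    for (s in seq_len(d[3])) out[, , s] <- resize_slice(unclass(v$mask)[, , s],
                                                        pre_cfg$target_size, TRUE)
    out
  })
  base_pairs <- volumes_to_slice_pairs(tx, ty)

  state <- init_train_state(gen_cfg = gen_cfg, disc_cfg = disc_cfg)
  initial_val_dice <- if (length(vx)) pooled_val_dice(state$generator, vx, vy) else NA_real_
  best_dice <- -Inf; best_epoch <- 0L
  history <- NULL

  for (epoch in seq_len(cfg$epochs)) {
    lr_e <- if (cfg$use_lr_schedule) cfg$lr * cfg$lr_schedule_decay^(epoch - 1L) else cfg$lr
    pairs <- expand_dataset(base_pairs, aug_cfg)
    pairs <- pairs[sample.int(length(pairs))]
    state$step_log <- NULL
    for (b in seq(1L, length(pairs), by = cfg$batch_size)) {
      batch <- pairs[b:min(b + cfg$batch_size - 1L, length(pairs))]
      state <- train_step(batch, state, cfg, lr = lr_e)
    }
    vd <- if (length(vx)) pooled_val_dice(state$generator, vx, vy) else NA_real_
    ep_means <- colMeans(state$step_log)
    history <- rbind(history,
                     data.frame(epoch = epoch, g_total = ep_means[["g_total"]],
                                g_adv = ep_means[["g_adv"]], g_l1 = ep_means[["g_l1"]],
                                d_loss = ep_means[["d_loss"]], val_dice = vd))
    if (verbose) {
      message(sprintf("epoch %3d  g_total %.4f  g_adv %.4f  g_l1 %.4f  d %.4f  val dice %.4f",
                      epoch, ep_means[["g_total"]], ep_means[["g_adv"]],
                      ep_means[["g_l1"]], ep_means[["d_loss"]], vd))
    }
    state$epoch <- epoch
    if (is.finite(vd) && vd > best_dice) { best_dice <- vd; best_epoch <- epoch }
    if (is.finite(cfg$patience) && epoch - best_epoch >= cfg$patience) break
  }
  list(generator = state$generator, discriminator = state$discriminator,
       history = history, initial_val_dice = initial_val_dice)
}

#' Segment a volume with a trained generator
#'
#' Each slice is preprocessed, passed through the generator (dropout off),
#' and binarized at the tanh midpoint 0.
#'
#' @param generator a generator `network_handle`.
#' @param volume a [volume_stack()] or 3D array on the raw 0-255 scale.
#' @param pre_cfg a [preprocess_config()] matching the one used in training.
#' @param native_size resize the predicted masks back to the input
#'   resolution (nearest-neighbour).
#' @param dropout_at_inference keep the bottleneck dropout (the GAN noise
#'   source) active during inference; off by default.
#' @return a binary mask [volume_stack()].
#' @export
predict_volume <- function(generator, volume, pre_cfg = preprocess_config(),
                           native_size = FALSE, dropout_at_inference = FALSE) {
  vol <- unclass(volume)
  d <- dim(vol)
  x <- preprocess_volume(vol, pre_cfg, is_mask = FALSE)
  side <- if (native_size) d[1] else pre_cfg$target_size
  out <- array(0L, c(side, side, d[3]))
  for (s in seq_len(d[3])) {
    pred <- generator_forward(generator, as_chw1(x[, , s]),
                              training = dropout_at_inference,
                              keep_cols = FALSE)$y
    m <- matrix(as.integer(pred[, , 1] > 0), dim(pred)[1], dim(pred)[2])
    if (native_size) m <- resize_slice(m, d[1], is_mask = TRUE)
    out[, , s] <- m
  }
  volume_stack(out, attr(volume, "spacing_mm") %||% 0.5)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
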