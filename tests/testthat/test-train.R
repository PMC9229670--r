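test_that("L1 loss is the mean absolute difference", {
  expect_equal(l1_loss(array(1, 8), array(1, 8)), 0)
  expect_equal(l1_loss(array(1, 8), array(-1, 8)), 2)
  expect_equal(l1_loss(c(0.5, -0.5), c(1, -1)), 0.5)
  expect_error(l1_loss(array(1, c(2, 2)), array(1, c(2, 3))), "shapes differ")
})

test_that("the generator objective decomposes as adversarial + lambda * L1", {
  d_half <- array(0.5, c(4, 4, 1))
  same <- array(0.2, c(8, 8, 1))
  g <- generator_loss(d_half, same, same, lambda_l1 = 75)
  expect_equal(g$total, -log(0.5), tolerance = 1e-12)
  expect_equal(g$l1, 0)
  pred <- array(0.1, c(8, 8, 1)); targ <- array(0, c(8, 8, 1))
  g2 <- generator_loss(d_half, pred, targ, lambda_l1 = 75)
  expect_equal(g2$total, -log(0.5) + 75 * 0.1, tolerance = 1e-9)
  expect_equal(g2$total, g2$adv + 75 * g2$l1)          # exact decomposition
  g0 <- generator_loss(d_half, pred, targ, lambda_l1 = 0)
  expect_equal(g0$total, g0$adv)
  expect_error(generator_loss(array(1.5, 4), pred, targ), "strictly in")
})

test_that("the discriminator objective is paced binary cross-entropy", {
  expect_lt(discriminator_loss(array(1 - 1e-9, 4), array(1e-9, 4), 0.5), 1e-5)
  expect_equal(discriminator_loss(array(0.5, 4), array(0.5, 4), 0.5),
               0.5 * -log(0.5), tolerance = 1e-12)
  set.seed(301)
  r <- array(stats::runif(16, 0.1, 0.9), c(4, 4, 1))
  f <- array(stats::runif(16, 0.1, 0.9), c(4, 4, 1))
  expect_equal(discriminator_loss(r, f, 0.5),
               discriminator_loss(1 - f, 1 - r, 0.5), tolerance = 1e-12)
})

test_that("alternating updates respect the freeze contract", {
  set.seed(302)
  state <- init_train_state(gen_cfg = micro_gen_cfg(), disc_cfg = micro_disc_cfg())
  vols <- micro_volumes(1L, seed = 40L)
  x <- preprocess_volume(unclass(vols[[1]]$image), micro_pre_cfg())
  y <- preprocess_volume(unclass(vols[[1]]$mask), micro_pre_cfg(), is_mask = TRUE)
  batch <- list(list(image = x[, , 1], mask = y[, , 1]),
                list(image = x[, , 2], mask = y[, , 2]))
  cfg <- micro_train_cfg()

  g_before <- state$generator$params; d_before <- state$discriminator$params
  s_g <- train_step(batch, state, cfg, update = "g")
  expect_identical(s_g$discriminator$params, d_before)   # D frozen in G step
  expect_false(identical(s_g$generator$params, g_before))
  s_d <- train_step(batch, state, cfg, update = "d")
  expect_identical(s_d$generator$params, g_before)       # G frozen in D step
  expect_false(identical(s_d$discriminator$params, d_before))

  s_both <- train_step(batch, state, cfg)
  expect_false(identical(s_both$generator$params, g_before))
  expect_false(identical(s_both$discriminator$params, d_before))
  expect_true(all(is.finite(unlist(s_both$step_log))))

  # degenerate optimizer: zero learning rate leaves weights untouched
  s0 <- train_step(batch, state, cfg, lr = 0)
  expect_identical(s0$generator$params, g_before)
  expect_identical(s0$discriminator$params, d_before)
  expect_equal(nrow(s0$step_log), 1L)
})

test_that("training is reproducible and improves validation Dice on phantoms", {
  vols <- micro_volumes(3L, seed = 50L, n_slices = 4L)
  run <- function() fit(vols[1:2], vols[3], micro_gen_cfg(), micro_disc_cfg(),
                        micro_train_cfg(epochs = 2L), micro_pre_cfg(),
                        micro_aug_cfg())
  r1 <- run(); r2 <- run()
  expect_identical(r1$history, r2$history)               # fully seeded
  expect_true(all(is.finite(unlist(r1$history[-1]))))
  expect_error(fit(list(), vols[3]), "empty training set")
})

test_that("early stopping never trains past best epoch + patience", {
  vols <- micro_volumes(2L, seed = 60L)
  res <- fit(vols[1], vols[2], micro_gen_cfg(), micro_disc_cfg(),
             micro_train_cfg(epochs = 6L, patience = 2L),
             micro_pre_cfg(), micro_aug_cfg())
  best <- which.max(res$history$val_dice)
  expect_lte(nrow(res$history), best + 2L)
})

test_that("volume prediction yields congruent strictly binary stacks", {
  set.seed(303)
  gen <- build_generator(micro_gen_cfg(), seed = 6)
  vols <- micro_volumes(1L, seed = 70L)
  pred <- predict_volume(gen, vols[[1]]$image, micro_pre_cfg())
  expect_identical(dim(unclass(pred)), c(16L, 16L, 2L))
  expect_true(all(unclass(pred) %in% c(0L, 1L)))
  # native-resolution output matches the input grid
  predn <- predict_volume(gen, vols[[1]]$image, micro_pre_cfg(),
                          native_size = TRUE)
  expect_identical(dim(unclass(predn)), dim(unclass(vols[[1]]$image)))
  # a generator biased hard negative yields an empty mask on pure background
  gen$params$net2$out$b[] <- -10
  bg <- generate_phantom_volume(phantom_config(n_vessels = 0L, n_slices = 2L,
                                               height = 16L, width = 16L,
                                               seed = 2L))
  empty <- predict_volume(gen, volume_stack(unclass(bg$image) * 255, 0.5),
                          micro_pre_cfg())
  expect_equal(sum(unclass(empty)), 0)
})
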