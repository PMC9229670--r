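# The layer library is the numerical foundation of the whole model, so every
# backward pass is checked against central finite differences of its own
# forward pass -- an oracle that shares no code with the implementation.

ns <- asNamespace("vesselgan")

proj_loss <- function(y, R) sum(y * R)

test_that("convolution gradients match finite differences", {
  set.seed(101)
  x <- array(stats::rnorm(8 * 8 * 3), c(8, 8, 3))
  W <- array(stats::rnorm(36, sd = 0.4), c(3, 3, 3, 4))
  b <- stats::rnorm(4)
  for (stride in c(1L, 2L)) {
    out <- ns$conv_forward(x, W, b, stride)
    R <- array(stats::rnorm(length(out$y)), dim(out$y))
    g <- ns$conv_backward(R, W, out$cache)
    eps <- 1e-5
    idx <- sample(length(x), 6)
    num <- vapply(idx, function(i) {
      xp <- x; xp[i] <- xp[i] + eps; xm <- x; xm[i] <- xm[i] - eps
      (proj_loss(ns$conv_forward(xp, W, b, stride)$y, R) -
       proj_loss(ns$conv_forward(xm, W, b, stride)$y, R)) / (2 * eps)
    }, numeric(1))
    expect_equal(g$dx[idx], num, tolerance = 1e-6)
    widx <- sample(length(W), 6)
    numw <- vapply(widx, function(i) {
      Wp <- W; Wp[i] <- Wp[i] + eps; Wm <- W; Wm[i] <- Wm[i] - eps
      (proj_loss(ns$conv_forward(x, Wp, b, stride)$y, R) -
       proj_loss(ns$conv_forward(x, Wm, b, stride)$y, R)) / (2 * eps)
    }, numeric(1))
    expect_equal(g$dW[widx], numw, tolerance = 1e-6)
    expect_equal(g$db, colSums(matrix(R, ncol = 4)), tolerance = 1e-10)
  }
})

test_that("transposed convolution doubles the grid and its gradients check out", {
  set.seed(102)
  x <- array(stats::rnorm(6 * 6 * 3), c(6, 6, 3))
  W <- array(stats::rnorm(3 * 3 * 5 * 3, sd = 0.4), c(3, 3, 5, 3))
  b <- stats::rnorm(5)
  out <- ns$deconv_forward(x, W, b, 2L)
  expect_identical(dim(out$y), c(12L, 12L, 5L))
  R <- array(stats::rnorm(length(out$y)), dim(out$y))
  g <- ns$deconv_backward(R, W, out$cache)
  eps <- 1e-5
  idx <- sample(length(x), 6)
  num <- vapply(idx, function(i) {
    xp <- x; xp[i] <- xp[i] + eps; xm <- x; xm[i] <- xm[i] - eps
    (proj_loss(ns$deconv_forward(xp, W, b, 2L)$y, R) -
     proj_loss(ns$deconv_forward(xm, W, b, 2L)$y, R)) / (2 * eps)
  }, numeric(1))
  expect_equal(g$dx[idx], num, tolerance = 1e-6)
  widx <- sample(length(W), 6)
  numw <- vapply(widx, function(i) {
    Wp <- W; Wp[i] <- Wp[i] + eps; Wm <- W; Wm[i] <- Wm[i] - eps
    (proj_loss(ns$deconv_forward(x, Wp, b, 2L)$y, R) -
     proj_loss(ns$deconv_forward(x, Wm, b, 2L)$y, R)) / (2 * eps)
  }, numeric(1))
  expect_equal(g$dW[widx], numw, tolerance = 1e-6)
})

test_that("instance norm normalizes per channel and backpropagates exactly", {
  set.seed(103)
  x <- array(stats::rnorm(7 * 7 * 3, mean = 2, sd = 3), c(7, 7, 3))
  gam <- stats::runif(3, 0.5, 1.5); bet <- stats::rnorm(3)
  out <- ns$instnorm_forward(x, gam, bet)
  xm <- matrix(out$y, ncol = 3)
  expect_equal(colMeans(xm), bet, tolerance = 1e-6)
  pop_sd <- apply(xm, 2, stats::sd) * sqrt(48 / 49)   # population variance
  expect_equal(pop_sd / gam, c(1, 1, 1), tolerance = 1e-3)
  R <- array(stats::rnorm(length(out$y)), dim(out$y))
  g <- ns$instnorm_backward(R, gam, out$cache)
  eps <- 1e-5
  idx <- sample(length(x), 8)
  num <- vapply(idx, function(i) {
    xp <- x; xp[i] <- xp[i] + eps; xm_ <- x; xm_[i] <- xm_[i] - eps
    (proj_loss(ns$instnorm_forward(xp, gam, bet)$y, R) -
     proj_loss(ns$instnorm_forward(xm_, gam, bet)$y, R)) / (2 * eps)
  }, numeric(1))
  expect_equal(g$dx[idx], num, tolerance = 1e-4)
})

test_that("single-conv parameter counts follow kernel * channels + bias", {
  set.seed(104)
  expect_equal(count_parameters(list(ns$init_conv(3L, 3L, 1L, 1L))), 10)
  expect_equal(count_parameters(list(ns$init_conv(4L, 4L, 1L, 8L))), 136)
})

test_that("whole-network gradients match finite differences", {
  set.seed(105)
  gen <- build_generator(generator_config(base_filters = 3L, levels = 2L,
                                          dropout_p = 0, input_size = 16L),
                         seed = 3)
  x <- array(stats::rnorm(16 * 16), c(16, 16, 1))
  out <- ns$generator_forward(gen, x, training = FALSE, keep_cols = TRUE)
  R <- array(stats::rnorm(length(out$y)), dim(out$y))
  gb <- ns$generator_backward(gen, R, out$cache)
  fp <- flat_paths(gen$params); fg <- flat_paths(gb$grads)
  expect_setequal(names(fp), names(fg))
  # skip bias-into-instance-norm leaves: their true gradient is exactly zero
  # and finite differences only return float noise there
  checkable <- names(fp)[!grepl("(down/conv|up/deconv|refine/conv[12]?)/b$", names(fp))]
  for (nm in sample(checkable, 15)) {
    leaf <- fp[[nm]]; i <- sample(length(leaf$val), 1)
    f <- function(d) {
      g2 <- gen
      g2$params <- perturb_leaf(g2$params, leaf$path, i, d)
      proj_loss(ns$generator_forward(g2, x, FALSE, FALSE)$y, R)
    }
    num <- (f(1e-5) - f(-1e-5)) / 2e-5
    expect_equal(fg[[nm]]$val[i], num, tolerance = 1e-4,
                 label = paste("generator grad at", nm))
  }

  disc <- build_discriminator(discriminator_config(base_filters = 3L,
                                                   levels = 2L, dropout_p = 0),
                              seed = 4)
  x2 <- array(stats::rnorm(16 * 16 * 2), c(16, 16, 2))
  outd <- ns$discriminator_forward(disc, x2, training = FALSE, keep_cols = TRUE)
  Rd <- array(stats::rnorm(length(outd$logits)), dim(outd$logits))
  db <- ns$discriminator_backward(disc, Rd, outd$cache)
  fpd <- flat_paths(disc$params); fgd <- flat_paths(db$grads)
  checkable <- names(fpd)[!grepl("conv/b$", names(fpd))]
  for (nm in checkable) {
    leaf <- fpd[[nm]]; i <- sample(length(leaf$val), 1)
    f <- function(d) {
      d2 <- disc
      d2$params <- perturb_leaf(d2$params, leaf$path, i, d)
      proj_loss(ns$discriminator_forward(d2, x2, FALSE, FALSE)$logits, Rd)
    }
    num <- (f(1e-5) - f(-1e-5)) / 2e-5
    expect_equal(fgd[[nm]]$val[i], num, tolerance = 1e-4,
                 label = paste("discriminator grad at", nm))
  }
  idx <- sample(length(x2), 6)
  num <- vapply(idx, function(i) {
    xp <- x2; xp[i] <- xp[i] + 1e-5; xm <- x2; xm[i] <- xm[i] - 1e-5
    (proj_loss(ns$discriminator_forward(disc, xp)$logits, Rd) -
     proj_loss(ns$discriminator_forward(disc, xm)$logits, Rd)) / 2e-5
  }, numeric(1))
  expect_equal(db$dx[idx], num, tolerance = 1e-5)
})
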