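## Generator and discriminator architectures.
##
## The generator chains two U-Net-shaped subnets. Subnet 1 is a classic
## U-Net: per level a stride-2 3x3 convolution followed by a refining 3x3
## convolution (instance norm + LeakyReLU after each), channels doubling per
## level; the decoder mirrors it with stride-2 3x3 transposed convolutions
## and concatenation skip connections. Subnet 2 has the same topology but
## every refining convolution is replaced by a residual block, and skips are
## merged by addition so the block's F(x) + x channel congruence holds.
## Dropout in both bottlenecks plays the role of the GAN noise input z.
## The discriminator is a PatchGAN: a ladder of stride-2 4x4 convolutions
## ending in a single-filter same-padded convolution + sigmoid, so a
## 256x256 input yields a 16x16 map of patch-level real/fake probabilities.

#' Generator configuration
#'
#' Defaults are calibrated so that the full-size generator carries about
#' 65 million trainable parameters for 256x256 single-channel input.
#'
#' @param in_channels number of input image channels.
#' @param levels number of stride-2 resolution stages per subnet.
#' @param base_filters channel width at the first level; doubles per level.
#' @param dropout_p dropout probability at each subnet bottleneck (the noise
#'   source of the conditional GAN).
#' @param negative_slope LeakyReLU slope for negative inputs.
#' @param variant `"uur"` (U-Net followed by residual U-Net, the full model),
#'   `"single_unet"` (subnet 1 alone) or `"concat_unets"` (architecturally
#'   identical to `"uur"`; the name used when the same generator is trained
#'   without an adversary).
#' @param input_size declared input side length; must be divisible by
#'   `2^levels`.
#' @return a `generator_config` list.
#' @export
generator_config <- function(in_channels = 1L, levels = 4L, base_filters = 119L,
                             dropout_p = 0.1, negative_slope = 0.2,
                             variant = c("uur", "single_unet", "concat_unets"),
                             input_size = 256L) {
  variant <- match.arg(variant)
  stopifnot(levels >= 1L, dropout_p >= 0, dropout_p < 1, base_filters >= 1L)
  if (input_size %% (2L^levels) != 0L) {
    stop("input side ", input_size, " is not divisible by 2^levels = ", 2L^levels,
         call. = FALSE)
  }
  structure(list(in_channels = as.integer(in_channels), levels = as.integer(levels),
                 base_filters = as.integer(base_filters), dropout_p = dropout_p,
                 negative_slope = negative_slope, variant = variant,
                 input_size = as.integer(input_size)),
            class = "generator_config")
}

#' Discriminator configuration
#'
#' Defaults are calibrated so the discriminator carries about 6.9 million
#' trainable parameters; four stride-2 levels reduce a 256x256 input to the
#' 16x16 patch-probability map.
#'
#' @param in_channels input channels (conditioning slice + mask = 2).
#' @param filter_size convolution kernel side (4).
#' @param levels number of stride-2 stages.
#' @param base_filters channel width at the first level.
#' @param dropout_p dropout before the final convolution.
#' @param negative_slope LeakyReLU slope.
#' @return a `discriminator_config` list.
#' @export
discriminator_config <- function(in_channels = 2L, filter_size = 4L, levels = 4L,
                                 base_filters = 101L, dropout_p = 0.1,
                                 negative_slope = 0.2) {
  stopifnot(levels >= 1L, filter_size >= 1L, base_filters >= 1L)
  structure(list(in_channels = as.integer(in_channels),
                 filter_size = as.integer(filter_size), levels = as.integer(levels),
                 base_filters = as.integer(base_filters), dropout_p = dropout_p,
                 negative_slope = negative_slope),
            class = "discriminator_config")
}

## ---- residual block ------------------------------------------------------

init_resblock <- function(c) {
  list(conv1 = init_conv(3L, 3L, c, c), norm1 = init_instnorm(c),
       conv2 = init_conv(3L, 3L, c, c), norm2 = init_instnorm(c))
}

#' Residual block forward pass
#'
#' Computes `LeakyReLU(F(x) + x)` where
#' `F(x) = IN(conv3x3(LeakyReLU(IN(conv3x3(x)))))`, all convolutions
#' same-padded and channel-preserving, so the output has exactly the shape of
#' the input.
#'
#' @param x feature array, dim `(H, W, C)`.
#' @param weights parameter list with elements `conv1`, `norm1`, `conv2`,
#'   `norm2` (as produced inside [build_generator()]).
#' @param slope LeakyReLU negative slope.
#' @param keep_cols retain caches needed for the backward pass.
#' @return `list(y, cache)`.
#' @export
residual_block <- function(x, weights, slope = 0.2, keep_cols = TRUE) {
  if (dim(x)[3] != dim(weights$conv1$W)[3]) {
    stop("residual block channel mismatch: input has ", dim(x)[3],
         " channels, weights expect ", dim(weights$conv1$W)[3], call. = FALSE)
  }
  c1 <- conv_forward(x, weights$conv1$W, weights$conv1$b, 1L, keep_cols)
  n1 <- instnorm_forward(c1$y, weights$norm1$gamma, weights$norm1$beta)
  a1 <- lrelu_forward(n1$y, slope)
  c2 <- conv_forward(a1$y, weights$conv2$W, weights$conv2$b, 1L, keep_cols)
  n2 <- instnorm_forward(c2$y, weights$norm2$gamma, weights$norm2$beta)
  s <- n2$y + x
  out <- lrelu_forward(s, slope)
  list(y = out$y,
       cache = list(c1 = c1$cache, n1 = n1$cache, a1 = a1$cache,
                    c2 = c2$cache, n2 = n2$cache, act = out$cache))
}

resblock_backward <- function(dy, weights, cache, slope = 0.2) {
  ds <- lrelu_backward(dy, cache$act, slope)
  n2 <- instnorm_backward(ds, weights$norm2$gamma, cache$n2)
  c2 <- conv_backward(n2$dx, weights$conv2$W, cache$c2)
  da1 <- lrelu_backward(c2$dx, cache$a1, slope)
  n1 <- instnorm_backward(da1, weights$norm1$gamma, cache$n1)
  c1 <- conv_backward(n1$dx, weights$conv1$W, cache$c1)
  list(dx = c1$dx + ds,
       grads = list(conv1 = list(W = c1$dW, b = c1$db),
                    norm1 = list(gamma = n1$dgamma, beta = n1$dbeta),
                    conv2 = list(W = c2$dW, b = c2$db),
                    norm2 = list(gamma = n2$dgamma, beta = n2$dbeta)))
}

## ---- conv + instance norm + LeakyReLU unit ------------------------------

cnl_forward <- function(p, x, stride, slope, keep_cols = TRUE) {
  cv <- conv_forward(x, p$conv$W, p$conv$b, stride, keep_cols)
  nm <- instnorm_forward(cv$y, p$norm$gamma, p$norm$beta)
  ac <- lrelu_forward(nm$y, slope)
  list(y = ac$y, cache = list(cv = cv$cache, nm = nm$cache, ac = ac$cache))
}

cnl_backward <- function(p, dy, cache, slope) {
  da <- lrelu_backward(dy, cache$ac, slope)
  nm <- instnorm_backward(da, p$norm$gamma, cache$nm)
  cv <- conv_backward(nm$dx, p$conv$W, cache$cv)
  list(dx = cv$dx,
       grads = list(conv = list(W = cv$dW, b = cv$db),
                    norm = list(gamma = nm$dgamma, beta = nm$dbeta)))
}

dnl_forward <- function(p, x, slope) {
  dc <- deconv_forward(x, p$deconv$W, p$deconv$b, 2L)
  nm <- instnorm_forward(dc$y, p$norm$gamma, p$norm$beta)
  ac <- lrelu_forward(nm$y, slope)
  list(y = ac$y, cache = list(dc = dc$cache, nm = nm$cache, ac = ac$cache))
}

dnl_backward <- function(p, dy, cache, slope) {
  da <- lrelu_backward(dy, cache$ac, slope)
  nm <- instnorm_backward(da, p$norm$gamma, cache$nm)
  dc <- deconv_backward(nm$dx, p$deconv$W, cache$dc)
  list(dx = dc$dx,
       grads = list(deconv = list(W = dc$dW, b = dc$db),
                    norm = list(gamma = nm$dgamma, beta = nm$dbeta)))
}

## ---- U-Net subnet --------------------------------------------------------

unet_init <- function(in_ch, f, levels, residual) {
  ch <- f * 2L^(seq_len(levels) - 1L)            # width per level
  enc <- vector("list", levels)
  prev <- in_ch
  for (i in seq_len(levels)) {
    enc[[i]] <- list(down = list(conv = init_conv(3L, 3L, prev, ch[i]),
                                 norm = init_instnorm(ch[i])),
                     refine = if (residual) init_resblock(ch[i]) else
                       list(conv = init_conv(3L, 3L, ch[i], ch[i]),
                            norm = init_instnorm(ch[i])))
    prev <- ch[i]
  }
  dec <- vector("list", levels)                   # stored deep -> shallow
  for (j in seq_len(levels)) {
    i <- levels - j + 1L                          # level being upsampled from
    cin <- ch[i]
    cout <- if (i > 1L) ch[i - 1L] else f
    dec[[j]] <- list(up = list(deconv = init_deconv(3L, 3L, cout, cin),
                               norm = init_instnorm(cout)),
                     refine = if (residual) init_resblock(cout) else
                       list(conv = init_conv(3L, 3L, if (i > 1L) 2L * cout else cout, cout),
                            norm = init_instnorm(cout)))
  }
  list(enc = enc, dec = dec, out = init_conv(3L, 3L, f, 1L))
}

unet_forward <- function(p, x, residual, slope, dropout_p, training,
                         keep_cols = TRUE) {
  levels <- length(p$enc)
  skips <- vector("list", levels)
  ecache <- vector("list", levels)
  h <- x
  for (i in seq_len(levels)) {
    dn <- cnl_forward(p$enc[[i]]$down, h, 2L, slope, keep_cols)
    if (residual) {
      rf <- residual_block(dn$y, p$enc[[i]]$refine, slope, keep_cols)
    } else {
      rf <- cnl_forward(p$enc[[i]]$refine, dn$y, 1L, slope, keep_cols)
    }
    ecache[[i]] <- list(down = dn$cache, refine = rf$cache)
    skips[[i]] <- rf$y
    h <- rf$y
  }
  dp <- dropout_forward(h, dropout_p, training)
  h <- dp$y
  dcache <- vector("list", levels)
  for (j in seq_len(levels)) {
    i <- levels - j + 1L
    up <- dnl_forward(p$dec[[j]]$up, h, slope)
    h <- up$y
    if (residual) {
      if (i > 1L) h <- h + skips[[i - 1L]]
      rf <- residual_block(h, p$dec[[j]]$refine, slope, keep_cols)
    } else {
      ns <- dim(h)[3]
      if (i > 1L) {
        h <- array(c(h, skips[[i - 1L]]), dim = dim(h) + c(0L, 0L, dim(skips[[i - 1L]])[3]))
      }
      rf <- cnl_forward(p$dec[[j]]$refine, h, 1L, slope, keep_cols)
    }
    dcache[[j]] <- list(up = up$cache, refine = rf$cache,
                        up_channels = if (!residual) ns else NULL)
    h <- rf$y
  }
  oc <- conv_forward(h, p$out$W, p$out$b, 1L, keep_cols)
  th <- tanh_forward(oc$y)
  list(y = th$y,
       cache = list(enc = ecache, drop = dp$cache, dec = dcache,
                    out = oc$cache, tanh = th$cache, residual = residual))
}

unet_backward <- function(p, dy, cache, slope) {
  levels <- length(p$enc)
  residual <- cache$residual
  g <- list(enc = vector("list", levels), dec = vector("list", levels))
  skip_grads <- vector("list", levels)

  doc <- tanh_backward(dy, cache$tanh)
  oc <- conv_backward(doc, p$out$W, cache$out)
  g$out <- list(W = oc$dW, b = oc$db)
  dh <- oc$dx
  for (j in rev(seq_len(levels))) {
    i <- levels - j + 1L
    if (residual) {
      rb <- resblock_backward(dh, p$dec[[j]]$refine, cache$dec[[j]]$refine, slope)
      dh <- rb$dx
      if (i > 1L) {
        sg <- dh                              # additive skip: gradient passes through
        skip_grads[[i - 1L]] <- if (is.null(skip_grads[[i - 1L]])) sg else skip_grads[[i - 1L]] + sg
      }
      g$dec[[j]] <- list(up = NULL, refine = rb$grads)
    } else {
      rb <- cnl_backward(p$dec[[j]]$refine, dh, cache$dec[[j]]$refine, slope)
      dh <- rb$dx
      if (i > 1L) {
        nup <- cache$dec[[j]]$up_channels
        dcat <- dh
        dh <- dcat[, , seq_len(nup), drop = FALSE]
        sg <- dcat[, , -seq_len(nup), drop = FALSE]
        skip_grads[[i - 1L]] <- if (is.null(skip_grads[[i - 1L]])) sg else skip_grads[[i - 1L]] + sg
      }
      g$dec[[j]] <- list(up = NULL, refine = rb$grads)
    }
    up <- dnl_backward(p$dec[[j]]$up, dh, cache$dec[[j]]$up, slope)
    g$dec[[j]]$up <- up$grads
    dh <- up$dx
  }
  dh <- dropout_backward(dh, cache$drop)
  for (i in rev(seq_len(levels))) {
    if (!is.null(skip_grads[[i]])) dh <- dh + skip_grads[[i]]
    if (residual) {
      rf <- resblock_backward(dh, p$enc[[i]]$refine, cache$enc[[i]]$refine, slope)
      g$enc[[i]] <- list(down = NULL, refine = rf$grads)
    } else {
      rf <- cnl_backward(p$enc[[i]]$refine, dh, cache$enc[[i]]$refine, slope)
      g$enc[[i]] <- list(down = NULL, refine = rf$grads)
    }
    dn <- cnl_backward(p$enc[[i]]$down, rf$dx, cache$enc[[i]]$down, slope)
    g$enc[[i]]$down <- dn$grads
    dh <- dn$dx
  }
  list(dx = dh, grads = g)
}

## ---- builders ------------------------------------------------------------

#' Build the segmentation generator
#'
#' @param cfg a [generator_config()].
#' @param seed optional integer; when given, weight initialisation is run
#'   under this seed so rebuilds are identical.
#' @return a `network_handle` holding the role, config and parameter tree.
#' @export
build_generator <- function(cfg = generator_config(), seed = NULL) {
  stopifnot(inherits(cfg, "generator_config"))
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  f <- cfg$base_filters
  params <- switch(cfg$variant,
    single_unet = list(net1 = unet_init(cfg$in_channels, f, cfg$levels, FALSE)),
    list(net1 = unet_init(cfg$in_channels, f, cfg$levels, FALSE),
         net2 = unet_init(1L, f, cfg$levels, TRUE)))
  structure(list(role = "generator", config = cfg, params = params),
            class = "network_handle")
}

#' Build the PatchGAN discriminator
#'
#' @param cfg a [discriminator_config()].
#' @param seed optional integer seed for reproducible initialisation.
#' @return a `network_handle`.
#' @export
build_discriminator <- function(cfg = discriminator_config(), seed = NULL) {
  stopifnot(inherits(cfg, "discriminator_config"))
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  g <- cfg$base_filters; k <- cfg$filter_size
  ch <- g * 2L^(seq_len(cfg$levels) - 1L)
  prev <- cfg$in_channels
  levels <- vector("list", cfg$levels)
  for (i in seq_len(cfg$levels)) {
    levels[[i]] <- list(conv = init_conv(k, k, prev, ch[i]),
                        norm = init_instnorm(ch[i]))
    prev <- ch[i]
  }
  params <- list(levels = levels, final = init_conv(k, k, prev, 1L))
  structure(list(role = "discriminator", config = cfg, params = params),
            class = "network_handle")
}

#' Count trainable parameters of a network
#'
#' Sums the sizes of every trainable weight array (convolution kernels and
#' biases, instance-norm scales and shifts).
#'
#' @param net a `network_handle`, or a bare parameter tree.
#' @return integer parameter count.
#' @export
count_parameters <- function(net) {
  params <- if (inherits(net, "network_handle")) net$params else net
  tree_sum(params, length)
}

#' @export
print.network_handle <- function(x, ...) {
  cat(sprintf("<%s network: %s trainable parameters>\n", x$role,
              format(count_parameters(x), big.mark = ",")))
  invisible(x)
}

## ---- whole-network forward/backward -------------------------------------

generator_forward <- function(net, x, training = FALSE, keep_cols = training) {
  cfg <- net$config
  d <- dim(x)
  if (is.null(d)) d <- c(dim(as.matrix(x)), 1L)
  if (length(d) == 2L) { dim(x) <- c(d, 1L); d <- dim(x) }
  if (d[1] %% (2L^cfg$levels) != 0L || d[2] %% (2L^cfg$levels) != 0L) {
    stop("generator input side must be divisible by 2^levels = ", 2L^cfg$levels,
         call. = FALSE)
  }
  f1 <- unet_forward(net$params$net1, x, FALSE, cfg$negative_slope,
                     cfg$dropout_p, training, keep_cols)
  if (cfg$variant == "single_unet") {
    return(list(y = f1$y, cache = list(c1 = f1$cache, c2 = NULL)))
  }
  f2 <- unet_forward(net$params$net2, f1$y, TRUE, cfg$negative_slope,
                     cfg$dropout_p, training, keep_cols)
  list(y = f2$y, cache = list(c1 = f1$cache, c2 = f2$cache))
}

generator_backward <- function(net, dy, cache) {
  cfg <- net$config
  if (is.null(cache$c2)) {
    b1 <- unet_backward(net$params$net1, dy, cache$c1, cfg$negative_slope)
    return(list(grads = list(net1 = b1$grads)))
  }
  b2 <- unet_backward(net$params$net2, dy, cache$c2, cfg$negative_slope)
  b1 <- unet_backward(net$params$net1, b2$dx, cache$c1, cfg$negative_slope)
  list(grads = list(net1 = b1$grads, net2 = b2$grads))
}

discriminator_forward <- function(net, x, training = FALSE, keep_cols = training) {
  cfg <- net$config
  lcache <- vector("list", cfg$levels)
  h <- x
  for (i in seq_len(cfg$levels)) {
    st <- cnl_forward(net$params$levels[[i]], h, 2L, cfg$negative_slope, keep_cols)
    lcache[[i]] <- st$cache
    h <- st$y
  }
  dp <- dropout_forward(h, cfg$dropout_p, training)
  fin <- conv_forward(dp$y, net$params$final$W, net$params$final$b, 1L, keep_cols)
  list(prob = sigmoid(fin$y), logits = fin$y,
       cache = list(levels = lcache, drop = dp$cache, final = fin$cache))
}

discriminator_backward <- function(net, dlogits, cache) {
  cfg <- net$config
  fin <- conv_backward(dlogits, net$params$final$W, cache$final)
  g <- list(levels = vector("list", cfg$levels),
            final = list(W = fin$dW, b = fin$db))
  dh <- dropout_backward(fin$dx, cache$drop)
  for (i in rev(seq_len(cfg$levels))) {
    st <- cnl_backward(net$params$levels[[i]], dh, cache$levels[[i]], cfg$negative_slope)
    g$levels[[i]] <- st$grads
    dh <- st$dx
  }
  list(dx = dh, grads = g)
}
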