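## Low-level differentiable layers.
##
## Every operation works on one sample at a time: activations are numeric
## arrays with dim (H, W, C), convolution weights have dim (kh, kw, Cin, Cout)
## and transposed-convolution weights dim (kh, kw, Cout, Cin). Forward
## functions return list(y, cache); backward functions take the upstream
## gradient and return the input gradient plus parameter gradients. Gradients
## are exact (verified against finite differences in the test suite).

#' @useDynLib vesselgan, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

# TensorFlow-style "same" padding: output side ceil(H / stride), with the
# extra padding pixel (odd totals) placed at the bottom/right.
same_pad <- function(size, k, stride) {
  out <- ceiling(size / stride)
  total <- max(0L, (out - 1L) * stride + k - size)
  c(before = total %/% 2L, out = out)
}

conv_out_shape <- function(H, W, k, stride) {
  ph <- same_pad(H, k, stride)
  pw <- same_pad(W, k, stride)
  list(Ho = ph[["out"]], Wo = pw[["out"]], pt = ph[["before"]], pl = pw[["before"]])
}

#' 2D convolution forward pass (same padding)
#'
#' @param x input array, dim `(H, W, Cin)`.
#' @param W weight array, dim `(kh, kw, Cin, Cout)`.
#' @param b bias vector, length `Cout`.
#' @param stride integer stride (same in both directions).
#' @param keep_cols keep the unrolled patch matrix in the cache (needed for
#'   the weight gradient during training).
#' @return `list(y, cache)` with `y` of dim `(H/stride, W/stride, Cout)`.
#' @keywords internal
conv_forward <- function(x, W, b, stride = 1L, keep_cols = TRUE) {
  d <- dim(x); dw <- dim(W)
  stopifnot(length(d) == 3L, length(dw) == 4L, d[3] == dw[3])
  g <- conv_out_shape(d[1], d[2], dw[1], stride)
  cols <- cpp_im2col(x, d[1], d[2], d[3], dw[1], dw[2], stride, stride,
                     g$pt, g$pl, g$Ho, g$Wo)
  y <- cols %*% matrix(W, nrow = prod(dw[1:3]))
  y <- y + rep(b, each = g$Ho * g$Wo)
  dim(y) <- c(g$Ho, g$Wo, dw[4])
  cache <- list(x_dim = d, w_dim = dw, stride = stride, geom = g,
                cols = if (keep_cols) cols else NULL, x = if (keep_cols) NULL else x)
  list(y = y, cache = cache)
}

#' 2D convolution backward pass
#' @keywords internal
conv_backward <- function(dy, W, cache) {
  d <- cache$x_dim; dw <- cache$w_dim; g <- cache$geom
  dym <- matrix(dy, nrow = g$Ho * g$Wo)
  cols <- cache$cols
  if (is.null(cols)) {
    cols <- cpp_im2col(cache$x, d[1], d[2], d[3], dw[1], dw[2],
                       cache$stride, cache$stride, g$pt, g$pl, g$Ho, g$Wo)
  }
  dW <- crossprod(cols, dym)
  dim(dW) <- dw
  db <- colSums(dym)
  dxm <- dym %*% t(matrix(W, nrow = prod(dw[1:3])))
  dx <- cpp_col2im(dxm, d[1], d[2], d[3], dw[1], dw[2],
                   cache$stride, cache$stride, g$pt, g$pl, g$Ho, g$Wo)
  list(dx = dx, dW = dW, db = db)
}

#' Transposed 2D convolution forward pass (stride-2 upsampling)
#'
#' Implements the adjoint of a same-padded strided convolution, so an input
#' of side `H` maps to side `H * stride`. Weights have dim
#' `(kh, kw, Cout, Cin)`: the layer maps `Cin` channels to `Cout`.
#' @keywords internal
deconv_forward <- function(x, W, b, stride = 2L) {
  d <- dim(x); dw <- dim(W)
  stopifnot(length(d) == 3L, d[3] == dw[4])
  Ho <- d[1] * stride; Wo <- d[2] * stride
  g <- conv_out_shape(Ho, Wo, dw[1], stride)   # geometry of the adjoint conv
  stopifnot(g$Ho == d[1], g$Wo == d[2])
  xm <- matrix(x, nrow = d[1] * d[2])
  ym <- xm %*% t(matrix(W, nrow = prod(dw[1:3])))
  y <- cpp_col2im(ym, Ho, Wo, dw[3], dw[1], dw[2], stride, stride,
                  g$pt, g$pl, d[1], d[2])
  y <- y + rep(b, each = Ho * Wo)   # channel-wise bias via recycling
  list(y = y, cache = list(x = x, x_dim = d, w_dim = dw, stride = stride,
                           geom = g, out_dim = c(Ho, Wo, dw[3])))
}

#' Transposed 2D convolution backward pass
#' @keywords internal
deconv_backward <- function(dy, W, cache) {
  d <- cache$x_dim; dw <- cache$w_dim; g <- cache$geom; od <- cache$out_dim
  cols <- cpp_im2col(dy, od[1], od[2], od[3], dw[1], dw[2],
                     cache$stride, cache$stride, g$pt, g$pl, d[1], d[2])
  Wm <- matrix(W, nrow = prod(dw[1:3]))
  dx <- cols %*% Wm
  dim(dx) <- d
  dW <- crossprod(cols, matrix(cache$x, nrow = d[1] * d[2]))
  dim(dW) <- dw
  db <- colSums(matrix(dy, ncol = od[3]))
  list(dx = dx, dW = dW, db = db)
}

#' Instance normalization (per-sample, per-channel) with affine parameters
#' @keywords internal
instnorm_forward <- function(x, gamma, beta, eps = 1e-5) {
  d <- dim(x)
  n <- d[1] * d[2]
  xm <- matrix(x, ncol = d[3])
  mu <- colMeans(xm)
  xc <- xm - rep(mu, each = n)
  v <- colMeans(xc * xc)
  istd <- 1 / sqrt(v + eps)
  xhat <- xc * rep(istd, each = n)
  y <- xhat * rep(gamma, each = n) + rep(beta, each = n)
  dim(y) <- d
  list(y = y, cache = list(xhat = xhat, istd = istd, dim = d))
}

instnorm_backward <- function(dy, gamma, cache) {
  d <- cache$dim
  dym <- matrix(dy, ncol = d[3])
  xhat <- cache$xhat
  dgamma <- colSums(dym * xhat)
  dbeta <- colSums(dym)
  n <- d[1] * d[2]
  # dx = gamma/std * (dy - mean(dy) - xhat * mean(dy * xhat))
  t1 <- dym - rep(dbeta / n, each = n)
  t2 <- xhat * rep(dgamma / n, each = n)
  dx <- (t1 - t2) * rep(gamma * cache$istd, each = n)
  dim(dx) <- d
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

lrelu_forward <- function(x, slope = 0.2) {
  pos <- x > 0
  list(y = x * (slope + (1 - slope) * pos), cache = pos)
}

lrelu_backward <- function(dy, cache, slope = 0.2) {
  dy * (slope + (1 - slope) * cache)
}

tanh_forward <- function(x) {
  y <- tanh(x)
  list(y = y, cache = y)
}

tanh_backward <- function(dy, cache) dy * (1 - cache^2)

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Inverted dropout; identity when `training = FALSE` or `p = 0`
#' @keywords internal
dropout_forward <- function(x, p, training) {
  if (!training || p <= 0) return(list(y = x, cache = NULL))
  keep <- array(stats::rbinom(length(x), 1L, 1 - p), dim(x)) / (1 - p)
  list(y = x * keep, cache = keep)
}

dropout_backward <- function(dy, cache) {
  if (is.null(cache)) dy else dy * cache
}

## ---- parameter initialisation -------------------------------------------

# He-normal fan-in initialisation; fan counts the receptive field, so it is
# the same formula for conv and transposed-conv weights.
init_conv <- function(kh, kw, cin, cout) {
  list(W = array(stats::rnorm(kh * kw * cin * cout, sd = sqrt(2 / (kh * kw * cin))),
                 dim = c(kh, kw, cin, cout)),
       b = numeric(cout))
}

init_deconv <- function(kh, kw, cout, cin) {
  list(W = array(stats::rnorm(kh * kw * cout * cin, sd = sqrt(2 / (kh * kw * cin))),
                 dim = c(kh, kw, cout, cin)),
       b = numeric(cout))
}

init_instnorm <- function(c) list(gamma = rep(1, c), beta = numeric(c))

## ---- parameter-tree helpers ---------------------------------------------

# Parameters, gradients and optimizer state all share one nested-list shape
# with numeric-array leaves; these helpers walk such trees in lockstep.

tree_map <- function(f, a) {
  if (is.list(a)) lapply(a, function(el) tree_map(f, el)) else f(a)
}

tree_map2 <- function(f, a, b) {
  if (is.list(a)) {
    out <- vector("list", length(a))
    names(out) <- names(a)
    for (i in seq_along(a)) out[[i]] <- tree_map2(f, a[[i]], b[[i]])
    out
  } else {
    f(a, b)
  }
}

tree_add <- function(a, b) tree_map2(`+`, a, b)
tree_scale <- function(a, s) tree_map(function(x) x * s, a)
tree_zeros_like <- function(a) tree_map(function(x) x * 0, a)

tree_sum <- function(a, f = identity) {
  total <- 0
  walk <- function(el) {
    if (is.list(el)) lapply(el, walk) else total <<- total + f(el)
    invisible(NULL)
  }
  walk(a)
  total
}
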