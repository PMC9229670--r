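# Independent brute-force oracles and micro fixtures shared across tests.
# Oracles are deliberately naive re-derivations (sliding windows, explicit
# loops) so they share no code with the implementation they check.

# Morphological closure oracle: dilation (outside = background) followed by
# erosion (outside = foreground), each as an explicit k x k sliding window.
bf_dilate <- function(m, k) {
  h <- nrow(m); w <- ncol(m); r <- k %/% 2
  p <- matrix(0, h + 2 * r, w + 2 * r)
  p[(r + 1):(r + h), (r + 1):(r + w)] <- m
  out <- matrix(0, h, w)
  for (i in 1:h) for (j in 1:w) out[i, j] <- max(p[i:(i + 2 * r), j:(j + 2 * r)])
  out
}

bf_erode <- function(m, k) {
  h <- nrow(m); w <- ncol(m); r <- k %/% 2
  p <- matrix(1, h + 2 * r, w + 2 * r)
  p[(r + 1):(r + h), (r + 1):(r + w)] <- m
  out <- matrix(0, h, w)
  for (i in 1:h) for (j in 1:w) out[i, j] <- min(p[i:(i + 2 * r), j:(j + 2 * r)])
  out
}

bf_closure <- function(m, k) bf_erode(bf_dilate(m, k), k)

# Global histogram equalization oracle (256 bins) on the 0-1 scale.
bf_global_equalize <- function(x, bins = 256L) {
  b <- pmin(floor(x * bins), bins - 1L)
  cdf <- cumsum(tabulate(b + 1L, bins)) / length(b)
  matrix(cdf[b + 1L], nrow(x), ncol(x))
}

# Parameter-tree walking for finite-difference gradient checks.
flat_paths <- function(p, prefix = character(0)) {
  res <- list()
  if (is.list(p)) {
    nms <- names(p)
    if (is.null(nms)) nms <- rep("", length(p))
    for (i in seq_along(p)) {
      nm <- if (nzchar(nms[i])) nms[i] else as.character(i)
      res <- c(res, flat_paths(p[[i]], c(prefix, nm)))
    }
    res
  } else {
    stats::setNames(list(list(path = prefix, val = p)),
                    paste(prefix, collapse = "/"))
  }
}

perturb_leaf <- function(tree, path, i, delta) {
  k <- if (grepl("^[0-9]+$", path[1])) as.integer(path[1]) else path[1]
  if (length(path) == 1L) tree[[k]][i] <- tree[[k]][i] + delta
  else tree[[k]] <- perturb_leaf(tree[[k]], path[-1], i, delta)
  tree
}

# Micro study fixtures: small phantoms and network configs that keep
# training-loop tests fast while exercising every code path.
micro_phantom_cfg <- function(seed = 1L, n_slices = 2L) {
  phantom_config(n_slices = n_slices, height = 16L, width = 16L, n_vessels = 2L,
                 radius_range = c(1, 2), tortuosity = 0.2, seed = seed)
}

micro_volumes <- function(n = 2L, seed = 1L, n_slices = 2L) {
  ds <- phantom_dataset(micro_phantom_cfg(seed, n_slices), n)
  lapply(ds, function(v) list(
    image = volume_stack(unclass(v$image) * 255, 0.5),
    mask = v$mask))
}

micro_gen_cfg <- function() generator_config(base_filters = 2L, levels = 2L,
                                             input_size = 16L)
micro_disc_cfg <- function() discriminator_config(base_filters = 2L, levels = 2L)
micro_pre_cfg <- function() preprocess_config(target_size = 16L)
micro_train_cfg <- function(epochs = 1L, ...) {
  train_config(epochs = epochs, batch_size = 2L, seed = 9L, ...)
}
micro_aug_cfg <- function() augment_config(copies_per_sample = 1L, seed = 9L)
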