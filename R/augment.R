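## Training-set augmentation: mirror flips and random patch zooms.
##
## Both transforms are applied jointly to a slice and its mask so the
## geometric pairing is never broken; masks are resampled with
## nearest-neighbour interpolation and therefore stay strictly binary.
## Augmentation is meant for training folds only -- the split into training
## and validation volumes happens before any expansion.

#' Augmentation settings
#'
#' @param enable_flip include mirror flips.
#' @param enable_patch include random patch zooms.
#' @param zoom_range zoom factor interval; the default `(1, 2]` zooms between
#'   the original size and twice the size.
#' @param copies_per_sample augmented copies generated per original slice.
#' @param seed integer seed for the random zoom draws.
#' @return an `augment_config` list.
#' @export
augment_config <- function(enable_flip = TRUE, enable_patch = TRUE,
                           zoom_range = c(1, 2), copies_per_sample = 2L,
                           seed = 42L) {
  stopifnot(length(zoom_range) == 2L, zoom_range[1] >= 1,
            zoom_range[1] <= zoom_range[2], copies_per_sample >= 0L)
  structure(list(enable_flip = isTRUE(enable_flip),
                 enable_patch = isTRUE(enable_patch),
                 zoom_range = as.numeric(zoom_range),
                 copies_per_sample = as.integer(copies_per_sample),
                 seed = as.integer(seed)),
            class = "augment_config")
}

#' Mirror-flip a slice/mask pair
#'
#' Reflects both about the vertical axis (left-right), the anatomically
#' plausible flip for a laterally symmetric brain.
#'
#' @param img numeric matrix.
#' @param mask congruent matrix (typically 0/1).
#' @return `list(image, mask)`, both flipped identically.
#' @export
mirror_flip <- function(img, mask) {
  if (!all(dim(img) == dim(mask))) {
    stop("image and mask shapes differ", call. = FALSE)
  }
  rev_cols <- rev(seq_len(ncol(img)))
  list(image = img[, rev_cols, drop = FALSE], mask = mask[, rev_cols, drop = FALSE])
}

#' Random zoom into a random patch of a slice/mask pair
#'
#' Draws a zoom factor `z` uniformly from `zoom_range`, crops a window of
#' side `round(side / z)` at a uniformly drawn origin, and resizes the window
#' back to the full slice size (bilinear for the image, nearest-neighbour for
#' the mask). The identical window is applied to both members of the pair.
#'
#' @param img numeric matrix.
#' @param mask congruent matrix.
#' @param cfg an [augment_config()]; only `zoom_range` is used.
#' @param zoom optional fixed zoom factor (overrides the random draw).
#' @param origin optional fixed `c(row, col)` window origin (1-based).
#' @return `list(image, mask)` at the original slice size.
#' @export
random_patch_zoom <- function(img, mask, cfg = augment_config(), zoom = NULL,
                              origin = NULL) {
  if (!all(dim(img) == dim(mask))) stop("image and mask shapes differ", call. = FALSE)
  h <- nrow(img); w <- ncol(img)
  z <- if (is.null(zoom)) stats::runif(1, cfg$zoom_range[1], cfg$zoom_range[2]) else zoom
  ph <- round(h / z); pw <- round(w / z)
  if (ph < 2 || pw < 2) stop("zoomed patch smaller than 2 pixels", call. = FALSE)
  if (is.null(origin)) {
    origin <- c(sample.int(h - ph + 1L, 1L), sample.int(w - pw + 1L, 1L))
  }
  ri <- origin[1]:(origin[1] + ph - 1L)
  ci <- origin[2]:(origin[2] + pw - 1L)
  pi_ <- img[ri, ci, drop = FALSE]
  pm <- mask[ri, ci, drop = FALSE]
  if (ph == h && pw == w) return(list(image = pi_, mask = pm))
  list(image = resize_slice(pi_, h, is_mask = FALSE),
       mask = resize_slice(pm, h, is_mask = TRUE))
}

#' Expand a list of slice/mask pairs with augmented copies
#'
#' The output keeps every original pair and appends `copies_per_sample`
#' augmented variants per slice, cycling through the enabled techniques
#' (flip first, then patch zoom).
#'
#' @param pairs list of `list(image, mask)` pairs.
#' @param cfg an [augment_config()].
#' @return the expanded list, length `n * (1 + copies_per_sample)`.
#' @export
expand_dataset <- function(pairs, cfg = augment_config()) {
  if (cfg$copies_per_sample == 0L) return(pairs)
  techniques <- c(if (cfg$enable_flip) "flip", if (cfg$enable_patch) "patch")
  if (!length(techniques)) return(pairs)
  out <- vector("list", length(pairs) * (1L + cfg$copies_per_sample))
  k <- 1L
  for (p in pairs) {
    out[[k]] <- p; k <- k + 1L
    for (cp in seq_len(cfg$copies_per_sample)) {
      tech <- techniques[(cp - 1L) %% length(techniques) + 1L]
      aug <- if (tech == "flip") mirror_flip(p$image, p$mask) else
        random_patch_zoom(p$image, p$mask, cfg)
      out[[k]] <- aug; k <- k + 1L
    }
  }
  out
}
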