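## Region-of-interest preprocessing.
##
## Angiographic slices carry low-level background noise outside the head.
## The ROI mask keeps pixels at or above an intensity threshold (default 10
## on the raw 0-255 scale), repairs holes with a morphological closure
## (default 9x9 square structuring element), and is multiplied into the
## slice. Slices are then resized to the network resolution and affinely
## mapped into the network input range (default [-1, 1], matching the
## generator's tanh output). CLAHE contrast enhancement is available as an
## option for low-contrast modalities such as two-photon microscopy.

#' Preprocessing settings
#'
#' @param threshold intensity threshold on the raw scale; pixels below it are
#'   zeroed when building the ROI mask.
#' @param closure_kernel odd side length of the structuring element used by
#'   the morphological closure.
#' @param kernel_shape `"box"` (square, the default reading of a bare kernel
#'   size) or `"disc"`.
#' @param target_size network input side length.
#' @param normalize_range two-element output interval for network input.
#' @param clahe_enabled apply CLAHE before masking.
#' @param clahe_clip CLAHE clip limit (multiple of the uniform histogram
#'   height, as used by [EBImage::clahe()]).
#' @param clahe_tiles number of contextual tiles per side.
#' @return a `preprocess_config` list.
#' @export
preprocess_config <- function(threshold = 10, closure_kernel = 9L,
                              kernel_shape = c("box", "disc"),
                              target_size = 256L, normalize_range = c(-1, 1),
                              clahe_enabled = FALSE, clahe_clip = 2,
                              clahe_tiles = 8L) {
  kernel_shape <- match.arg(kernel_shape)
  if (closure_kernel %% 2L != 1L || closure_kernel < 1L) {
    stop("closure_kernel must be an odd positive integer", call. = FALSE)
  }
  stopifnot(target_size >= 16L, length(normalize_range) == 2L,
            normalize_range[1] < normalize_range[2])
  structure(list(threshold = threshold, closure_kernel = as.integer(closure_kernel),
                 kernel_shape = kernel_shape, target_size = as.integer(target_size),
                 normalize_range = as.numeric(normalize_range),
                 clahe_enabled = isTRUE(clahe_enabled), clahe_clip = clahe_clip,
                 clahe_tiles = as.integer(clahe_tiles)),
            class = "preprocess_config")
}

#' Declare the intensity range of a slice
#'
#' @param img numeric matrix of pixel intensities.
#' @param range declared `(lo, hi)` intensity range.
#' @return the matrix with a `value_range` attribute.
#' @export
slice_image <- function(img, range = c(0, 255)) {
  stopifnot(is.matrix(img), all(is.finite(img)), length(range) == 2L)
  attr(img, "value_range") <- as.numeric(range)
  img
}

value_range_of <- function(img, default = c(0, 255)) {
  vr <- attr(img, "value_range")
  if (is.null(vr)) default else vr
}

#' Build the ROI mask of a slice
#'
#' Thresholds the slice (pixels `>= threshold` are kept) and applies a
#' morphological closure so that dark holes inside the head region are
#' filled. The closure is dilation followed by erosion with the configured
#' structuring element.
#'
#' @param img numeric matrix on the raw intensity scale the threshold refers
#'   to (default 0-255).
#' @param cfg a [preprocess_config()].
#' @return a 0/1 integer matrix of the same shape.
#' @export
make_roi_mask <- function(img, cfg = preprocess_config()) {
  vr <- value_range_of(img, default = c(0, 255))
  if (cfg$threshold < vr[1] || cfg$threshold > vr[2]) {
    warning("threshold ", cfg$threshold, " lies outside the declared intensity range [",
            vr[1], ", ", vr[2], "]; mask computed anyway", call. = FALSE)
  }
  bin <- matrix(as.numeric(img >= cfg$threshold), nrow(img), ncol(img))
  if (cfg$closure_kernel > 1L) {
    kern <- EBImage::makeBrush(cfg$closure_kernel,
                               shape = if (cfg$kernel_shape == "box") "box" else "disc")
    bin <- EBImage::closing(bin, kern)
  }
  storage.mode(bin) <- "integer"
  bin
}

#' Multiply a mask into a slice
#'
#' @param img numeric matrix.
#' @param mask congruent 0/1 matrix.
#' @return the elementwise product, preserving the declared value range.
#' @export
apply_mask <- function(img, mask) {
  if (!all(dim(img) == dim(mask))) {
    stop("image and mask shapes differ: ", paste(dim(img), collapse = "x"),
         " vs ", paste(dim(mask), collapse = "x"), call. = FALSE)
  }
  out <- img * mask
  attr(out, "value_range") <- attr(img, "value_range")
  out
}

#' Resize a slice or mask to a square target size
#'
#' Images are resampled with bilinear interpolation (pixel-centre aligned,
#' clamped at the borders); masks use nearest-neighbour sampling with the
#' top-left convention `src = floor(i * n / target)`, which keeps them
#' strictly binary.
#'
#' @param img numeric matrix.
#' @param target_size output side length.
#' @param is_mask use nearest-neighbour sampling.
#' @return a `target_size x target_size` matrix.
#' @export
resize_slice <- function(img, target_size, is_mask = FALSE) {
  stopifnot(is.matrix(img), target_size >= 1L)
  h <- nrow(img); w <- ncol(img); t <- as.integer(target_size)
  if (is_mask) {
    ri <- floor((seq_len(t) - 1L) * h / t) + 1L
    ci <- floor((seq_len(t) - 1L) * w / t) + 1L
    out <- img[ri, ci, drop = FALSE]
  } else {
    interp_axis <- function(n) {
      pos <- pmin(pmax((seq_len(t) - 0.5) * n / t - 0.5, 0), n - 1)
      lo <- pmin(floor(pos), n - 1)
      list(lo = lo + 1, hi = pmin(lo + 1, n - 1) + 1, w = pos - lo)
    }
    ay <- interp_axis(h); ax <- interp_axis(w)
    wy <- matrix(ay$w, t, t); wx <- matrix(ax$w, t, t, byrow = TRUE)
    out <- img[ay$lo, ax$lo, drop = FALSE] * (1 - wy) * (1 - wx) +
      img[ay$hi, ax$lo, drop = FALSE] * wy * (1 - wx) +
      img[ay$lo, ax$hi, drop = FALSE] * (1 - wy) * wx +
      img[ay$hi, ax$hi, drop = FALSE] * wy * wx
  }
  attr(out, "value_range") <- attr(img, "value_range")
  out
}

#' Contrast-limited adaptive histogram equalization
#'
#' Tile-wise histogram equalization with a clip limit, delegating to
#' [EBImage::clahe()]. A single-tile configuration is the limiting case of
#' plain global histogram equalization and is computed exactly as such.
#'
#' @param img numeric matrix; equalization runs on the declared intensity
#'   range (default taken from the `value_range` attribute, else the 0-1
#'   scale for float input).
#' @param cfg a [preprocess_config()]; fields `clahe_clip` and `clahe_tiles`.
#' @return matrix on the same scale as the input.
#' @export
clahe_enhance <- function(img, cfg = preprocess_config()) {
  vr <- value_range_of(img, default = c(0, if (max(img) > 1) 255 else 1))
  x <- (img - vr[1]) / (vr[2] - vr[1])
  if (stats::sd(x) == 0) return(img)          # no contrast to redistribute
  if (cfg$clahe_tiles <= 1L) {
    bins <- 256L
    b <- pmin(floor(x * bins), bins - 1L)
    cdf <- cumsum(tabulate(b + 1L, bins)) / length(b)
    y <- matrix(cdf[b + 1L], nrow(x), ncol(x))
  } else {
    y <- EBImage::clahe(x, nx = cfg$clahe_tiles, ny = cfg$clahe_tiles,
                        limit = cfg$clahe_clip, keep.range = FALSE)
    y <- pmin(pmax(y, 0), 1)
  }
  out <- y * (vr[2] - vr[1]) + vr[1]
  attr(out, "value_range") <- vr
  out
}

#' Affinely map a slice into the network input range
#'
#' @param img numeric matrix with a declared `value_range` (or `from_range`).
#' @param range two-element target interval, default `c(-1, 1)`.
#' @param from_range source interval; defaults to the declared value range.
#' @return matrix with values in `range` and the new range declared.
#' @export
normalize_for_network <- function(img, range = c(-1, 1), from_range = NULL) {
  vr <- if (is.null(from_range)) value_range_of(img) else from_range
  if (vr[1] == vr[2]) stop("degenerate declared range [", vr[1], ", ", vr[2], "]",
                           call. = FALSE)
  out <- (img - vr[1]) / (vr[2] - vr[1]) * (range[2] - range[1]) + range[1]
  attr(out, "value_range") <- as.numeric(range)
  out
}

#' Invert [normalize_for_network()]
#'
#' @param img normalized matrix.
#' @param range the interval it was normalized into.
#' @param to_range the original interval to map back onto.
#' @return matrix on the original scale.
#' @export
denormalize_from_network <- function(img, range = c(-1, 1), to_range = c(0, 255)) {
  out <- (img - range[1]) / (range[2] - range[1]) * (to_range[2] - to_range[1]) + to_range[1]
  attr(out, "value_range") <- as.numeric(to_range)
  out
}

#' Preprocess a whole volume for the network
#'
#' Runs the full chain on every slice: optional CLAHE, ROI masking, resize to
#' the network resolution, and normalization into the network range.
#'
#' @param vol a [volume_stack()] (or 3D array) on the raw intensity scale.
#' @param cfg a [preprocess_config()].
#' @param is_mask when `TRUE` the volume is a 0/1 mask: thresholding, CLAHE
#'   and ROI masking are skipped and resizing is nearest-neighbour; the mask
#'   is mapped into the network range so it can serve as a regression target.
#' @return a 3D array of `target_size` slices in the network range.
#' @export
preprocess_volume <- function(vol, cfg = preprocess_config(), is_mask = FALSE) {
  d <- dim(vol)
  out <- array(0, c(cfg$target_size, cfg$target_size, d[3]))
  for (s in seq_len(d[3])) {
    sl <- vol[, , s]
    if (is_mask) {
      sl <- resize_slice(sl, cfg$target_size, is_mask = TRUE)
      out[, , s] <- sl * (cfg$normalize_range[2] - cfg$normalize_range[1]) +
        cfg$normalize_range[1]
    } else {
      sl <- slice_image(sl, range = c(0, 255))
      if (cfg$clahe_enabled) sl <- clahe_enhance(sl, cfg)
      roi <- make_roi_mask(sl, cfg)
      sl <- apply_mask(sl, roi)
      sl <- resize_slice(sl, cfg$target_size, is_mask = FALSE)
      out[, , s] <- normalize_for_network(sl, cfg$normalize_range,
                                          from_range = c(0, 255))
    }
  }
  out
}
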