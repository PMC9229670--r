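## Synthetic vascular phantoms.
##
## TOF-MRA shows flowing blood as bright tubular structures on a noisy
## darker background, with vessel pixels vastly outnumbered by background.
## The phantom generator emulates exactly those properties: vessel
## centerlines are smoothed 3D random walks through the slice stack (so
## adjacent slices share structure, as in a real angiographic volume), tubes
## are rasterised by thresholding the exact 3D distance to the centerline
## (giving an analytic ground-truth mask), and the background is clipped
## additive Gaussian noise.

#' Phantom generation settings
#'
#' Defaults emulate a desk-scale angiographic volume: a handful of bright,
#' mildly tortuous vessels of 1.5-3 px radius over a dark noisy background,
#' giving a vessel-pixel fraction of a few percent (severe class imbalance).
#'
#' @param n_slices,height,width volume dimensions.
#' @param n_vessels number of vessel centerlines.
#' @param radius_range tube radius range in pixels, min >= 1.
#' @param vessel_intensity_range vessel brightness range on the 0-1 scale;
#'   the low end must exceed `background_mean + 2 * background_noise_sigma`
#'   so contrast is learnable.
#' @param background_mean,background_noise_sigma background Gaussian noise
#'   parameters on the 0-1 scale.
#' @param tortuosity nonnegative scale of the per-step angular perturbation
#'   of each centerline walk; 0 gives straight tubes.
#' @param spacing_mm inter-slice spacing recorded on generated volumes.
#' @param seed integer seed; the same config generates bit-identical output.
#' @return a `phantom_config` list.
#' @export
phantom_config <- function(n_slices = 32L, height = 64L, width = 64L,
                           n_vessels = 3L, radius_range = c(1.5, 3),
                           vessel_intensity_range = c(0.7, 0.95),
                           background_mean = 0.15, background_noise_sigma = 0.05,
                           tortuosity = 0.2, spacing_mm = 0.5, seed = 42L) {
  stopifnot(n_slices >= 1L, height >= 1L, width >= 1L, n_vessels >= 0L,
            length(radius_range) == 2L, radius_range[1] >= 1 || n_vessels == 0L,
            radius_range[1] <= radius_range[2],
            vessel_intensity_range[1] <= vessel_intensity_range[2],
            tortuosity >= 0)
  if (radius_range[2] > min(height, width) / 2) {
    stop("degenerate geometry: max vessel radius ", radius_range[2],
         " exceeds half the slice side ", min(height, width) / 2, call. = FALSE)
  }
  if (n_vessels > 0L &&
      vessel_intensity_range[1] <= background_mean + 2 * background_noise_sigma) {
    stop("vessel intensity low end must exceed background_mean + 2*sigma ",
         "to guarantee learnable contrast", call. = FALSE)
  }
  structure(list(n_slices = as.integer(n_slices), height = as.integer(height),
                 width = as.integer(width), n_vessels = as.integer(n_vessels),
                 radius_range = as.numeric(radius_range),
                 vessel_intensity_range = as.numeric(vessel_intensity_range),
                 background_mean = background_mean,
                 background_noise_sigma = background_noise_sigma,
                 tortuosity = tortuosity, spacing_mm = spacing_mm,
                 seed = as.integer(seed)),
            class = "phantom_config")
}

#' Volume stack container
#'
#' A light wrapper around a numeric `(height, width, n_slices)` array with
#' the inter-slice spacing attached.
#'
#' @param data 3D numeric array.
#' @param spacing_mm inter-slice spacing in millimetres.
#' @return a `volume_stack`.
#' @export
volume_stack <- function(data, spacing_mm = 0.5) {
  stopifnot(is.array(data), length(dim(data)) == 3L, all(is.finite(data)))
  structure(data, spacing_mm = spacing_mm, class = c("volume_stack", "array"))
}

#' @export
print.volume_stack <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<volume_stack %dx%d, %d slices, %.2f mm spacing, range [%.3g, %.3g]>\n",
              d[1], d[2], d[3], attr(x, "spacing_mm"), min(x), max(x)))
  invisible(x)
}

# Smoothed 3D random walk, reflected at the volume boundary. Returns a
# densely sampled polyline (one point every ~half step).
vessel_centerline <- function(cfg) {
  h <- cfg$height; w <- cfg$width; s <- cfg$n_slices
  pos <- c(stats::runif(1, 1, h), stats::runif(1, 1, w), stats::runif(1, 1, s))
  dir <- stats::rnorm(3)
  dir[3] <- dir[3] * (s / max(h, w))        # bias steps toward the slice plane
  dir <- dir / sqrt(sum(dir^2))
  n_steps <- 3L * max(h, w, s)
  step <- 0.5
  pts <- matrix(NA_real_, n_steps, 3L)
  lim <- c(h, w, s)
  for (t in seq_len(n_steps)) {
    dir <- dir + cfg$tortuosity * stats::rnorm(3) * step
    dir <- dir / sqrt(sum(dir^2))
    pos <- pos + step * dir
    ref <- pos < 1 | pos > lim              # reflect at boundaries
    dir[ref] <- -dir[ref]
    pos <- pmin(pmax(pos, 1), lim)
    pts[t, ] <- pos
  }
  pts
}

# Paint a tube of the given radius around a polyline into the mask and image.
rasterize_tube <- function(img, mask, pts, radius, intensity) {
  d <- dim(img)
  for (t in seq_len(nrow(pts))) {
    p <- pts[t, ]
    zr <- seq(max(1L, ceiling(p[3] - radius)), min(d[3], floor(p[3] + radius)))
    for (z in zr) {
      r2 <- radius^2 - (z - p[3])^2
      if (r2 <= 0) next
      r <- sqrt(r2)
      ir <- seq(max(1L, ceiling(p[1] - r)), min(d[1], floor(p[1] + r)))
      jr <- seq(max(1L, ceiling(p[2] - r)), min(d[2], floor(p[2] + r)))
      if (!length(ir) || !length(jr)) next
      dd <- outer((ir - p[1])^2, (jr - p[2])^2, "+")
      sel <- dd <= r2
      if (!any(sel)) next
      sub_m <- mask[ir, jr, z]
      sub_i <- img[ir, jr, z]
      sub_m[sel] <- 1
      sub_i[sel] <- intensity
      mask[ir, jr, z] <- sub_m
      img[ir, jr, z] <- sub_i
    }
  }
  list(img = img, mask = mask)
}

#' Generate one synthetic angiographic volume with its exact vessel mask
#'
#' @param cfg a [phantom_config()].
#' @return `list(image, mask)` of congruent [volume_stack()]s; the image is
#'   on the 0-1 scale and the mask is strictly 0/1.
#' @export
generate_phantom_volume <- function(cfg = phantom_config()) {
  stopifnot(inherits(cfg, "phantom_config"))
  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(cfg$seed)
  d <- c(cfg$height, cfg$width, cfg$n_slices)
  img <- array(pmin(pmax(stats::rnorm(prod(d), cfg$background_mean,
                                      cfg$background_noise_sigma), 0), 1), d)
  mask <- array(0, d)
  if (cfg$n_vessels > 0L) {
    for (v in seq_len(cfg$n_vessels)) {
      radius <- stats::runif(1, cfg$radius_range[1], cfg$radius_range[2])
      intensity <- stats::runif(1, cfg$vessel_intensity_range[1],
                                cfg$vessel_intensity_range[2])
      pts <- vessel_centerline(cfg)
      out <- rasterize_tube(img, mask, pts, radius, intensity)
      img <- out$img; mask <- out$mask
    }
    # mild intensity texture inside vessels, kept above the contrast floor
    nv <- sum(mask == 1)
    img[mask == 1] <- pmin(pmax(img[mask == 1] + stats::rnorm(nv, 0, 0.02),
                                cfg$vessel_intensity_range[1] - 0.05), 1)
  }
  list(image = volume_stack(img, cfg$spacing_mm),
       mask = volume_stack(mask, cfg$spacing_mm))
}

#' Generate a dataset of phantom volumes with derived per-volume seeds
#'
#' @param cfg a [phantom_config()]; its `seed` seeds the whole dataset.
#' @param n_volumes number of volumes.
#' @return list of `list(image, mask)` pairs, all with equal shapes.
#' @export
phantom_dataset <- function(cfg = phantom_config(), n_volumes = 4L) {
  stopifnot(n_volumes >= 1L)
  lapply(seq_len(n_volumes), function(i) {
    vcfg <- cfg
    vcfg$seed <- as.integer((cfg$seed + i * 9973) %% .Machine$integer.max)
    generate_phantom_volume(vcfg)
  })
}
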