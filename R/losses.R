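## Training objectives.
##
## The generator minimises a combined objective: the adversarial term (binary
## cross-entropy of the discriminator's patch map against all-real labels)
## plus lambda times the L1 distance between the generated and reference
## segmentation maps, with lambda = 75 weighting heavily toward L1 -- the
## regime that handles the extreme vessel/background class imbalance. The
## discriminator minimises standard real/fake binary cross-entropy, scaled by
## a pace factor of 0.5 so it optimises at half the generator's pace.

BCE_EPS <- 1e-7

bce_mean <- function(p, target) {
  p <- pmin(pmax(p, BCE_EPS), 1 - BCE_EPS)
  -mean(target * log(p) + (1 - target) * log(1 - p))
}

#' Mean absolute (L1) reconstruction loss
#'
#' @param pred,target congruent numeric arrays (any shape).
#' @return mean absolute difference over all elements.
#' @export
l1_loss <- function(pred, target) {
  if (!identical(dim(pred), dim(target)) || length(pred) != length(target)) {
    stop("prediction and target shapes differ", call. = FALSE)
  }
  mean(abs(pred - target))
}

#' Combined generator objective
#'
#' `total = adv + lambda * l1`, where `adv` is the mean binary cross-entropy
#' of the discriminator's output on the generated sample against all-ones
#' (real) labels, and `l1` is [l1_loss()] between prediction and target.
#'
#' @param d_on_fake discriminator probability map for the generated sample;
#'   values must lie in (0, 1).
#' @param pred,target generated and reference maps in the network range.
#' @param lambda_l1 weight of the L1 term (default 75).
#' @return `list(total, adv, l1)`.
#' @export
generator_loss <- function(d_on_fake, pred, target, lambda_l1 = 75) {
  if (any(d_on_fake <= 0 | d_on_fake >= 1)) {
    stop("discriminator outputs must lie strictly in (0, 1)", call. = FALSE)
  }
  adv <- bce_mean(d_on_fake, 1)
  l1 <- l1_loss(pred, target)
  list(total = adv + lambda_l1 * l1, adv = adv, l1 = l1)
}

#' Discriminator objective
#'
#' `pace_factor * (BCE(d_on_real, 1) + BCE(d_on_fake, 0)) / 2`; the default
#' pace factor 0.5 halves the discriminator's objective relative to the
#' generator's.
#'
#' @param d_on_real,d_on_fake probability maps for real and generated pairs;
#'   values at exactly 0 or 1 are epsilon-clamped.
#' @param pace_factor multiplier on the discriminator objective.
#' @return scalar loss.
#' @export
discriminator_loss <- function(d_on_real, d_on_fake, pace_factor = 0.5) {
  if (any(d_on_real < 0 | d_on_real > 1) || any(d_on_fake < 0 | d_on_fake > 1)) {
    stop("discriminator outputs must lie in [0, 1]", call. = FALSE)
  }
  pace_factor * 0.5 * (bce_mean(d_on_real, 1) + bce_mean(d_on_fake, 0))
}
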