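## Segmentation evaluation.
##
## All metrics derive from confusion counts pooled over every pixel of a
## compared stack (one number per validation volume, not a per-slice
## average): Dice 2TP/(2TP+FP+FN), precision TP/(TP+FP), sensitivity
## TP/(TP+FN), specificity TN/(TN+FP). Ratios with an empty denominator are
## reported as NA rather than silently as zero, so they cannot corrupt fold
## averages.

check_binary <- function(x, what) {
  ux <- unique(as.vector(x))
  if (!all(ux %in% c(0, 1))) {
    stop(what, " is not binary (values outside {0, 1})", call. = FALSE)
  }
}

#' Pooled pixelwise confusion counts between two binary stacks
#'
#' @param pred,truth congruent binary arrays (slices or volumes).
#' @return a `confusion_counts` list with fields `TP`, `FP`, `FN`, `TN`.
#' @export
confusion_counts <- function(pred, truth) {
  if (!identical(dim(pred), dim(truth)) || length(pred) != length(truth)) {
    stop("prediction and truth shapes differ", call. = FALSE)
  }
  check_binary(pred, "prediction"); check_binary(truth, "truth")
  p <- as.vector(pred) == 1; t <- as.vector(truth) == 1
  structure(list(TP = sum(p & t), FP = sum(p & !t),
                 FN = sum(!p & t), TN = sum(!p & !t)),
            class = "confusion_counts")
}

ratio_or_na <- function(num, den) if (den > 0) num / den else NA_real_

#' Dice score from confusion counts
#' @param counts a [confusion_counts()] object.
#' @return `2TP / (2TP + FP + FN)`, or `NA` when no positives exist anywhere.
#' @export
dice <- function(counts) {
  ratio_or_na(2 * counts$TP, 2 * counts$TP + counts$FP + counts$FN)
}

#' Precision (positive predictive value) from confusion counts
#' @param counts a [confusion_counts()] object.
#' @return `TP / (TP + FP)`, or `NA` when nothing was predicted positive.
#' @export
precision <- function(counts) ratio_or_na(counts$TP, counts$TP + counts$FP)

#' Sensitivity (recall) from confusion counts
#' @param counts a [confusion_counts()] object.
#' @return `TP / (TP + FN)`, or `NA` when the truth has no positives.
#' @export
sensitivity <- function(counts) ratio_or_na(counts$TP, counts$TP + counts$FN)

#' Specificity from confusion counts
#' @param counts a [confusion_counts()] object.
#' @return `TN / (TN + FP)`, or `NA` when the truth has no negatives.
#' @export
specificity <- function(counts) ratio_or_na(counts$TN, counts$TN + counts$FP)

#' Dice score computed directly from pixel sets
#'
#' Independent route to the same statistic: `2|A n B| / (|A| + |B|)` where A
#' and B are the positive-pixel sets. Agrees exactly with [dice()] on
#' confusion counts.
#'
#' @param pred,truth congruent binary arrays.
#' @return the set-formula Dice score, `NA` if both masks are empty.
#' @export
dice_set_equivalence <- function(pred, truth) {
  check_binary(pred, "prediction"); check_binary(truth, "truth")
  a <- sum(pred == 1); b <- sum(truth == 1)
  if (a + b == 0) return(NA_real_)
  2 * sum(pred == 1 & truth == 1) / (a + b)
}

#' Absolute-difference error map between truth and prediction
#'
#' @param pred,truth congruent binary arrays.
#' @return `|truth - pred|`; binary in, binary out, and its positive count
#'   equals `FP + FN`.
#' @export
error_map <- function(pred, truth) {
  if (!identical(dim(pred), dim(truth)) || length(pred) != length(truth)) {
    stop("prediction and truth shapes differ", call. = FALSE)
  }
  abs(truth - pred)
}

#' Full metrics report for a predicted stack
#'
#' @param pred,truth congruent binary arrays.
#' @return a `metrics_report` with Dice, precision, sensitivity, specificity
#'   and the underlying counts.
#' @export
metrics_report <- function(pred, truth) {
  cc <- confusion_counts(pred, truth)
  structure(list(dice = dice(cc), precision = precision(cc),
                 sensitivity = sensitivity(cc), specificity = specificity(cc),
                 counts = cc),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("Dice %.4f  Precision %.4f  Sensitivity %.4f  Specificity %.4f\n",
              x$dice, x$precision, x$sensitivity, x$specificity))
  cat(sprintf("  (TP %d  FP %d  FN %d  TN %d)\n",
              x$counts$TP, x$counts$FP, x$counts$FN, x$counts$TN))
  invisible(x)
}

#' Deterministic volume-to-fold assignment
#'
#' Volume `i` goes to fold `((i - 1) mod k) + 1`, cycling the volumes so each
#' is used exactly once for validation when `k == n`.
#'
#' @param n number of volumes.
#' @param k number of folds.
#' @return integer fold index per volume.
#' @export
fold_assignment <- function(n, k) {
  if (k > n) stop("k = ", k, " exceeds the number of volumes (", n, ")",
                  call. = FALSE)
  ((seq_len(n) - 1L) %% k) + 1L
}

#' Append the unweighted average row to a per-fold metrics table
#'
#' @param df data frame with a `fold` column and numeric metric columns.
#' @return the table with one extra `"Average"` row holding column means
#'   (`NA`s removed).
#' @export
summarize_folds <- function(df) {
  num <- vapply(df, is.numeric, logical(1)) & names(df) != "fold"
  avg <- df[1, , drop = FALSE]
  avg$fold <- "Average"
  for (cn in names(df)[num]) avg[[cn]] <- mean(df[[cn]], na.rm = TRUE)
  df$fold <- as.character(df$fold)
  rbind(df, avg)
}

#' k-fold cross-validation over volumes
#'
#' Trains one model per fold on the out-of-fold volumes and evaluates pooled
#' metrics on the fold's validation volumes, then appends the average row.
#' Hyperparameters are identical across folds.
#'
#' @param volumes list of `list(image, mask)` volume pairs (images on the raw
#'   0-255 scale, masks 0/1).
#' @param k number of folds (default 4).
#' @param gen_cfg,disc_cfg,cfg,pre_cfg,aug_cfg module configurations passed
#'   to [fit()].
#' @param verbose print per-epoch progress.
#' @return `list(table, fits)`: the per-fold + Average metrics table and the
#'   per-fold fit results.
#' @export
kfold_run <- function(volumes, k = 4L, gen_cfg = generator_config(),
                      disc_cfg = discriminator_config(), cfg = train_config(),
                      pre_cfg = preprocess_config(), aug_cfg = augment_config(),
                      verbose = FALSE) {
  folds <- fold_assignment(length(volumes), k)
  rows <- NULL; fits <- vector("list", k)
  for (fold in seq_len(k)) {
    train_v <- volumes[folds != fold]
    val_v <- volumes[folds == fold]
    res <- fit(train_v, val_v, gen_cfg, disc_cfg, cfg, pre_cfg, aug_cfg, verbose)
    tp <- fp <- fn <- tn <- 0
    for (v in val_v) {
      pred <- predict_volume(res$generator, v$image, pre_cfg)
      truth <- array(0L, dim(pred))
      for (s in seq_len(dim(pred)[3])) {
        truth[, , s] <- resize_slice(unclass(v$mask)[, , s],
                                     pre_cfg$target_size, is_mask = TRUE)
      }
      cc <- confusion_counts(unclass(pred), truth)
      tp <- tp + cc$TP; fp <- fp + cc$FP; fn <- fn + cc$FN; tn <- tn + cc$TN
    }
    cc <- structure(list(TP = tp, FP = fp, FN = fn, TN = tn),
                    class = "confusion_counts")
    rows <- rbind(rows, data.frame(fold = fold, dice = dice(cc),
                                   precision = precision(cc),
                                   sensitivity = sensitivity(cc),
                                   specificity = specificity(cc)))
    fits[[fold]] <- res
  }
  list(table = summarize_folds(rows), fits = fits)
}
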