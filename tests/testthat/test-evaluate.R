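test_that("confusion counts enumerate pixels and respect symmetry", {
  z <- array(0, c(4, 4))
  cc <- confusion_counts(z, z)
  expect_equal(cc$TN, 16); expect_equal(cc$TP + cc$FP + cc$FN, 0)
  cc2 <- confusion_counts(c(1, 1, 0, 0), c(1, 0, 1, 0))
  expect_equal(unlist(cc2[c("TP", "FP", "FN", "TN")]),
               c(TP = 1, FP = 1, FN = 1, TN = 1))
  # swapping prediction and truth swaps FP and FN, fixes TP and TN
  cc3 <- confusion_counts(c(1, 0, 1, 0), c(1, 1, 0, 0))
  expect_equal(cc3$FP, cc2$FN); expect_equal(cc3$FN, cc2$FP)
  expect_equal(cc3$TP, cc2$TP); expect_equal(cc3$TN, cc2$TN)
  expect_error(confusion_counts(c(1, 2), c(1, 0)), "not binary")
  expect_error(confusion_counts(array(0, c(2, 2)), array(0, c(2, 3))),
               "shapes differ")
})

test_that("metric formulas reproduce hand-enumerated count tuples", {
  cc <- function(tp, fp, fn, tn) structure(list(TP = tp, FP = fp, FN = fn, TN = tn),
                                           class = "confusion_counts")
  expect_equal(dice(cc(3, 1, 2, 10)), 6 / 9)
  expect_equal(dice(cc(5, 0, 0, 10)), 1)
  expect_equal(dice(cc(0, 3, 2, 10)), 0)
  expect_true(is.na(dice(cc(0, 0, 0, 10))))
  expect_equal(precision(cc(9, 1, 5, 0)), 0.9)
  expect_equal(sensitivity(cc(8, 3, 2, 0)), 0.8)
  expect_equal(specificity(cc(1, 0, 1, 7)), 1)
  expect_equal(specificity(cc(0, 5, 0, 15)), 0.75)
  expect_true(is.na(precision(cc(0, 0, 4, 4))))
  expect_true(is.na(sensitivity(cc(0, 4, 0, 4))))
  expect_true(is.na(specificity(cc(4, 0, 4, 0))))
})

test_that("count-based Dice equals the set formula on random mask pairs", {
  set.seed(401)
  for (t in 1:100) {
    d <- c(sample(3:8, 1), sample(3:8, 1))
    pred <- array(stats::rbinom(prod(d), 1, stats::runif(1)), d)
    truth <- array(stats::rbinom(prod(d), 1, stats::runif(1)), d)
    a <- dice(confusion_counts(pred, truth))
    b <- dice_set_equivalence(pred, truth)
    if (is.na(a)) expect_true(is.na(b)) else expect_identical(a, b)
  }
  one <- array(c(1, 1, 0, 0), c(2, 2))
  expect_equal(dice_set_equivalence(one, one), 1)
  expect_equal(dice_set_equivalence(one, 1 - one), 0)
})

test_that("error maps are the absolute difference with FP + FN positives", {
  set.seed(402)
  pred <- array(stats::rbinom(64, 1, 0.4), c(8, 8))
  truth <- array(stats::rbinom(64, 1, 0.4), c(8, 8))
  em <- error_map(pred, truth)
  expect_true(all(em %in% c(0, 1)))
  cc <- confusion_counts(pred, truth)
  expect_equal(sum(em), cc$FP + cc$FN)
  expect_true(all(error_map(truth, truth) == 0))
  expect_true(all(error_map(1 - truth, truth) == 1))
})

test_that("sparse-foreground phantoms sit in the high-specificity regime", {
  v <- generate_phantom_volume(phantom_config(seed = 31L))
  truth <- unclass(v$mask)
  # a prediction perturbed by a few percent of flips stays ~perfectly specific
  set.seed(403)
  pred <- truth
  flip <- sample(length(pred), round(0.02 * length(pred)))
  pred[flip] <- 1 - pred[flip]
  m <- metrics_report(pred, truth)
  expect_gt(m$specificity, 0.97)
  expect_true(all(unlist(m[c("dice", "precision", "sensitivity", "specificity")])
                  >= 0))
  expect_true(all(unlist(m[c("dice", "precision", "sensitivity", "specificity")])
                  <= 1))
})

test_that("fold assignment partitions volumes with each validating once", {
  f <- fold_assignment(4L, 4L)
  expect_identical(sort(unique(f)), 1:4)
  expect_identical(as.integer(table(f)), rep(1L, 4))
  f2 <- fold_assignment(8L, 4L)
  expect_true(all(table(f2) == 2))
  expect_error(fold_assignment(3L, 4L), "exceeds")
})

test_that("the average row is the arithmetic mean of the fold rows", {
  tab <- data.frame(fold = 1:4,
                    dice = c(0.8825, 0.8574, 0.8742, 0.8752),
                    precision = c(0.8789, 0.9064, 0.9141, 0.8817))
  out <- summarize_folds(tab)
  expect_identical(out$fold[5], "Average")
  expect_equal(out$dice[5], mean(tab$dice))
  expect_equal(round(out$dice[5], 4), 0.8723)
  expect_equal(round(out$precision[5], 4), 0.8953)
})

test_that("a k-fold run trains k models and reports a Table-shaped summary", {
  vols <- micro_volumes(4L, seed = 80L)
  res <- kfold_run(vols, k = 4L, micro_gen_cfg(), micro_disc_cfg(),
                   micro_train_cfg(), micro_pre_cfg(), micro_aug_cfg())
  tab <- res$table
  expect_equal(nrow(tab), 5L)
  expect_identical(tab$fold, c("1", "2", "3", "4", "Average"))
  expect_equal(tab$dice[5], mean(tab$dice[1:4]))
  expect_true(all(tab$specificity[1:4] >= 0 & tab$specificity[1:4] <= 1,
                  na.rm = TRUE))
  expect_length(res$fits, 4L)
})
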