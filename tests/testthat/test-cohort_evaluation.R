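test_that("confusion counts the four cells", {
  cm <- confusion(c(TRUE, TRUE, FALSE, FALSE), c(TRUE, FALSE, FALSE, TRUE))
  expect_equal(unlist(cm[c("tp", "fp", "tn", "fn")]),
               c(tp = 1, fp = 1, tn = 1, fn = 1))
  all_pos <- confusion(rep(TRUE, 5), rep(TRUE, 5))
  expect_equal(all_pos$fp + all_pos$fn, 0)
  pred <- rep(c(TRUE, FALSE, TRUE, FALSE), c(43, 6, 13, 176))
  tru <- rep(c(TRUE, TRUE, FALSE, FALSE), c(43, 6, 13, 176))
  cm2 <- confusion(pred, tru)
  expect_equal(unlist(cm2[c("tp", "fn", "fp", "tn")]),
               c(tp = 43, fn = 6, fp = 13, tn = 176))
  expect_error(confusion(TRUE, c(TRUE, FALSE)), "equal length")
  expect_error(confusion_matrix(-1, 0, 0, 0), "non-negative")
})

test_that("binary metrics reproduce hand-checked proportions with CIs", {
  # counts back-solved from the published od-cutoff row at 70 ml
  bm <- binary_metrics(confusion_matrix(tp = 43, fp = 13, tn = 176, fn = 6))
  est <- setNames(round_half_up(100 * bm$estimate, 1), bm$metric)
  expect_equal(est[["sensitivity"]], 87.8)
  expect_equal(est[["specificity"]], 93.1)
  expect_equal(est[["accuracy"]], 92.0)
  expect_equal(est[["ppv"]], 76.8)
  expect_equal(est[["npv"]], 96.7)
  # published ABC/2 row at 100 ml
  bm2 <- binary_metrics(confusion_matrix(tp = 35, fp = 14, tn = 187, fn = 2))
  est2 <- setNames(round_half_up(100 * bm2$estimate, 1), bm2$metric)
  expect_equal(est2[["sensitivity"]], 94.6)
  expect_equal(est2[["accuracy"]], 93.3)
  expect_equal(est2[["ppv"]], 71.4)
  expect_equal(est2[["npv"]], 98.9)
  # interval sanity: bounds in [0,1] and containing the estimate
  expect_true(all(bm$lower <= bm$estimate & bm$estimate <= bm$upper))
  expect_true(all(bm$lower >= 0 & bm$upper <= 1))
  # Wilson alternative stays close but not identical
  bw <- binary_metrics(confusion_matrix(43, 13, 176, 6), ci_method = "wilson")
  expect_equal(bw$estimate, bm$estimate)
  expect_false(isTRUE(all.equal(bw$lower, bm$lower)))
})

test_that("a perfect classifier scores 1.0 everywhere", {
  bm <- binary_metrics(confusion_matrix(tp = 1, fp = 0, tn = 1, fn = 0))
  expect_true(all(bm$estimate == 1))
})

test_that("zero denominators are flagged undefined, not coerced to 0", {
  bm <- binary_metrics(confusion_matrix(tp = 0, fp = 2, tn = 8, fn = 0))
  expect_true(bm$undefined[bm$metric == "sensitivity"])
  expect_true(is.na(bm$estimate[bm$metric == "sensitivity"]))
  expect_false(bm$undefined[bm$metric == "specificity"])
})

test_that("rank-based C-statistic matches the pairwise definition", {
  expect_equal(c_statistic(c(1, 2, 3, 4), c(FALSE, FALSE, TRUE, TRUE)), 1.0)
  expect_equal(c_statistic(rep(2, 6), rep(c(TRUE, FALSE), 3)), 0.5)
  expect_equal(c_statistic(c(1, 2, 2, 3), c(FALSE, TRUE, FALSE, TRUE)), 0.875)
  expect_error(c_statistic(1:4, rep(TRUE, 4)), "both classes")
  set.seed(404)
  for (rep in 1:40) {
    n <- sample(4:50, 1)
    scores <- sample(round(rnorm(n), sample(0:2, 1)))  # induce ties
    truth <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (all(truth) || !any(truth)) truth[1:2] <- c(TRUE, FALSE)
    expect_equal(c_statistic(scores, truth), brute_auc(scores, truth),
                 tolerance = 1e-12)
  }
})

test_that("median overestimation compares cohort medians in percent", {
  v <- c(10, 25, 40, 80)
  expect_equal(median_overestimation(v, v), 0)
  expect_equal(median_overestimation(2 * v, v), 100)
  expect_equal(median_overestimation(rep(33.8, 5), rep(26, 5)), 30,
               tolerance = 1e-3)
  expect_error(median_overestimation(v, rep(0, 4)), "zero")
})

test_that("integer confusion reconstruction inverts printed marginals", {
  cm <- reconstruct_confusion(238, 49, 87.8, 93.1)
  expect_equal(c(cm$tp, cm$tn), c(43, 176))
  cm2 <- reconstruct_confusion(238, 37, 70.3, 97.0)
  expect_equal(c(cm2$tp, cm2$tn), c(26, 195))
  cm3 <- reconstruct_confusion(10, 5, 100.0, 100.0)
  expect_equal(c(cm3$tp, cm3$tn), c(5, 5))
  # no integer count of 10 rounds to 55.0%
  expect_error(reconstruct_confusion(20, 10, 55.0, 100.0), "no integer")
  expect_error(reconstruct_confusion(10, 20, 50, 50), "\\[0, n\\]")
})

test_that("reconstructed matrices satisfy the accuracy identity", {
  marg <- reference_cohort_marginals()
  for (i in seq_len(nrow(marg))) {
    cm <- reconstruct_confusion(marg$n[i], marg$n_pos[i],
                                marg$sensitivity_pct[i],
                                marg$specificity_pct[i])
    bm <- binary_metrics(cm)
    prev <- marg$n_pos[i] / marg$n[i]
    sens <- bm$estimate[bm$metric == "sensitivity"]
    spec <- bm$estimate[bm$metric == "specificity"]
    acc <- bm$estimate[bm$metric == "accuracy"]
    expect_equal(acc, sens * prev + spec * (1 - prev), tolerance = 1e-12)
  }
})

test_that("cohort evaluation assembles all method-threshold cells", {
  set.seed(77)
  n <- 60
  manual <- rlnorm(n, log(40), 0.9)
  results <- data.frame(
    od_value = NA, od_volume_ml = manual * runif(n, 0.8, 1.2),
    abc2_volume_ml = manual * runif(n, 0.9, 1.5),
    manual_volume_ml = manual
  )
  results$od_value <- (sqrt(1.1^2 + 4 * 0.03 * results$od_volume_ml) - 1.1) /
    (2 * 0.03)  # invert the polynomial so classifications are coherent
  ev <- evaluate_cohort(results)
  expect_s3_class(ev, "cohort_evaluation")
  expect_equal(nrow(ev$metrics), 20)  # 2 methods x 2 thresholds x 5 metrics
  expect_equal(nrow(ev$c_statistics), 4)
  expect_true(all(ev$c_statistics$c_statistic >= 0 &
                  ev$c_statistics$c_statistic <= 1))
  expect_equal(sort(names(ev$confusions)),
               sort(c("od_cutoff_70ml", "od_cutoff_100ml",
                      "abc2_70ml", "abc2_100ml")))
  expect_error(evaluate_cohort(results[, -1]), "must contain")
})
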