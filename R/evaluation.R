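#' @title Diagnostic-accuracy evaluation
#' @description
#' The statistics used to compare the diameter-based estimators against
#' gold-standard volumetry at the >70 ml and >100 ml thresholds: 2x2
#' confusion matrices; sensitivity, specificity, accuracy, PPV and NPV with
#' binomial confidence intervals; the rank-based C-statistic; percent
#' overestimation of the median volume; and an integer reconstructor that
#' recovers a confusion matrix from published cohort marginals.
#' @name cohort-evaluation
NULL

#' Build a 2x2 confusion matrix
#'
#' @param predicted logical vector of classifier calls.
#' @param truth logical vector of gold-standard labels, same length.
#' @return An object of class `confusion_matrix` with integer counts
#'   `tp, fp, tn, fn` and `n`.
#' @export
confusion <- function(predicted, truth) {
  predicted <- as.logical(predicted); truth <- as.logical(truth)
  if (length(predicted) != length(truth))
    stop("`predicted` and `truth` must have equal length")
  if (length(predicted) < 1L) stop("need at least one case")
  if (anyNA(predicted) || anyNA(truth)) stop("NA labels are not allowed")
  confusion_matrix(
    tp = sum(predicted & truth), fp = sum(predicted & !truth),
    tn = sum(!predicted & !truth), fn = sum(!predicted & truth)
  )
}

#' @rdname confusion
#' @param tp,fp,tn,fn non-negative integer counts.
#' @export
confusion_matrix <- function(tp, fp, tn, fn) {
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("confusion counts must be non-negative integers")
  structure(as.list(c(counts, n = sum(counts))), class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("<confusion_matrix> tp=%d fp=%d tn=%d fn=%d (n=%d)\n",
              x$tp, x$fp, x$tn, x$fn, x$n))
  invisible(x)
}

# Binomial proportion with CI. Clopper-Pearson (exact, via binom.test) by
# default; Wilson score interval as the alternative. Zero denominator ->
# NA point estimate and bounds, flagged undefined rather than silently 0.
prop_ci <- function(x, n, level = 0.95, method = c("clopper-pearson", "wilson")) {
  method <- match.arg(method)
  if (n == 0)
    return(list(estimate = NA_real_, lower = NA_real_, upper = NA_real_,
                undefined = TRUE))
  est <- x / n
  if (method == "clopper-pearson") {
    ci <- binom.test(x, n, conf.level = level)$conf.int
    lower <- ci[1]; upper <- ci[2]
  } else {
    z <- qnorm(1 - (1 - level) / 2)
    den <- 1 + z^2 / n
    ctr <- (est + z^2 / (2 * n)) / den
    hw <- z * sqrt(est * (1 - est) / n + z^2 / (4 * n^2)) / den
    lower <- max(0, ctr - hw); upper <- min(1, ctr + hw)
  }
  list(estimate = est, lower = lower, upper = upper, undefined = FALSE)
}

#' Binary diagnostic metrics with confidence intervals
#'
#' Sensitivity `tp/(tp+fn)`, specificity `tn/(tn+fp)`, accuracy `(tp+tn)/n`,
#' PPV `tp/(tp+fp)` and NPV `tn/(tn+fn)`, each with a binomial confidence
#' interval — exact Clopper–Pearson by default, the standard conservative
#' choice for diagnostic studies, with the Wilson score interval available.
#' A metric whose denominator is zero is returned as `NA` and flagged.
#'
#' @param cm a [confusion_matrix].
#' @param ci_level confidence level (default 0.95).
#' @param ci_method `"clopper-pearson"` (default) or `"wilson"`.
#' @return A data frame with one row per metric: `metric, estimate, lower,
#'   upper, undefined`, proportions in `[0, 1]`.
#' @export
binary_metrics <- function(cm, ci_level = 0.95,
                           ci_method = c("clopper-pearson", "wilson")) {
  stopifnot(inherits(cm, "confusion_matrix"))
  ci_method <- match.arg(ci_method)
  defs <- list(
    sensitivity = c(cm$tp, cm$tp + cm$fn),
    specificity = c(cm$tn, cm$tn + cm$fp),
    accuracy    = c(cm$tp + cm$tn, cm$n),
    ppv         = c(cm$tp, cm$tp + cm$fp),
    npv         = c(cm$tn, cm$tn + cm$fn)
  )
  rows <- lapply(names(defs), function(nm) {
    p <- prop_ci(defs[[nm]][1], defs[[nm]][2], ci_level, ci_method)
    data.frame(metric = nm, estimate = p$estimate, lower = p$lower,
               upper = p$upper, undefined = p$undefined,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Rank-based C-statistic (area under the ROC curve)
#'
#' `P(score_pos > score_neg) + 0.5 * P(score_pos == score_neg)` over all
#' positive-negative pairs, computed via midranks (equivalent to the
#' Mann–Whitney U normalization, and exactly equal to the pairwise
#' definition including ties).
#'
#' @param scores continuous scores, higher meaning more likely positive.
#' @param truth logical labels; both classes must be present.
#' @return The C-statistic in `[0, 1]`.
#' @export
c_statistic <- function(scores, truth) {
  truth <- as.logical(truth)
  if (length(scores) != length(truth))
    stop("`scores` and `truth` must have equal length")
  if (anyNA(scores) || anyNA(truth)) stop("NA inputs are not allowed")
  n_pos <- sum(truth); n_neg <- sum(!truth)
  if (n_pos == 0L || n_neg == 0L)
    stop("C-statistic undefined: both classes must be present")
  r <- rank(scores)  # midranks handle ties as half-wins
  (sum(r[truth]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Percent overestimation of the median volume
#'
#' `100 * (median(est) - median(manual)) / median(manual)`: the cohort-level
#' bias summary used to compare estimators, positive when the estimator
#' overestimates.
#'
#' @param est_ml estimated volumes in ml.
#' @param manual_ml gold-standard volumes in ml, same length.
#' @return Percent over- (positive) or under-estimation (negative).
#' @export
median_overestimation <- function(est_ml, manual_ml) {
  if (length(est_ml) != length(manual_ml))
    stop("`est_ml` and `manual_ml` must have equal length")
  if (length(est_ml) < 1L) stop("need at least one case")
  m <- median(manual_ml)
  if (m == 0) stop("median manual volume is zero; overestimation undefined")
  100 * (median(est_ml) - m) / m
}

#' Reconstruct a confusion matrix from published marginals
#'
#' Given the cohort size, the number of truly positive cases, and the
#' printed sensitivity and specificity (percent, one decimal), finds the
#' integer `tp` and `tn` whose proportions round to the printed values —
#' letting accuracy, PPV and NPV of a published 2x2 table be recovered when
#' the raw data are unavailable.
#'
#' @param n cohort size.
#' @param n_pos number of truly positive cases, `0 <= n_pos <= n`.
#' @param sensitivity_pct,specificity_pct printed percentages in `[0, 100]`.
#' @return A [confusion_matrix]. Errors if no integer count matches a
#'   printed value at one-decimal rounding, or if the match is ambiguous.
#' @export
reconstruct_confusion <- function(n, n_pos, sensitivity_pct, specificity_pct) {
  if (n_pos < 0 || n_pos > n) stop("`n_pos` must lie in [0, n]")
  if (sensitivity_pct < 0 || sensitivity_pct > 100 ||
      specificity_pct < 0 || specificity_pct > 100)
    stop("percentages must lie in [0, 100]")
  pick <- function(total, target_pct, what) {
    if (total == 0L) stop("cannot reconstruct ", what, ": zero denominator")
    k <- 0:total
    hits <- which(round_half_up(100 * k / total, 1) == round_half_up(target_pct, 1))
    if (length(hits) == 0L)
      stop("no integer ", what, " count matches ", target_pct,
           "% at one-decimal rounding")
    if (length(hits) > 1L)
      stop("ambiguous reconstruction: ", length(hits), " ", what,
           " counts match ", target_pct, "% at one-decimal rounding")
    k[hits]
  }
  tp <- pick(n_pos, sensitivity_pct, "true-positive")
  tn <- pick(n - n_pos, specificity_pct, "true-negative")
  confusion_matrix(tp = tp, fp = (n - n_pos) - tn, tn = tn, fn = n_pos - tp)
}

#' Published marginals of the reference multicenter DWI cohort
#'
#' The four method-by-threshold rows of the reference diagnostic study of
#' diameter-based lesion-size estimation (n = 238 acute ischemic stroke
#' patients; 49 infarcts >70 ml, 37 >100 ml), as printed: prevalence plus
#' sensitivity and specificity to one decimal. Feeding these rows to
#' [reconstruct_confusion()] recovers the full 2x2 tables and hence the
#' published accuracy, PPV and NPV.
#'
#' @return A data frame with columns `method, threshold_ml, n, n_pos,
#'   sensitivity_pct, specificity_pct`.
#' @export
reference_cohort_marginals <- function() {
  data.frame(
    method = c("od_cutoff", "abc2", "od_cutoff", "abc2"),
    threshold_ml = c(70, 70, 100, 100),
    n = 238L,
    n_pos = c(49L, 49L, 37L, 37L),
    sensitivity_pct = c(87.8, 93.9, 70.3, 94.6),
    specificity_pct = c(93.1, 85.7, 97.0, 93.0),
    stringsAsFactors = FALSE
  )
}

#' Evaluate estimator performance over a cohort
#'
#' Computes, for each method (od-cutoff, ABC/2) and each threshold (70 ml,
#' 100 ml), the confusion matrix against gold-standard volumetry and the
#' five binary metrics with CIs; plus the C-statistic of each continuous
#' volume score against each threshold's truth, and the percent
#' overestimation of the median volume for each estimator.
#'
#' @param results per-patient results data frame as produced by
#'   [run_patient()] / [run_cohort()] (needs columns `od_value`,
#'   `od_volume_ml`, `abc2_volume_ml`, `manual_volume_ml`).
#' @param config a [threshold_config].
#' @param ci_level,ci_method passed to [binary_metrics()].
#' @return An object of class `cohort_evaluation`: `metrics` (long data
#'   frame: method, threshold_ml, metric, estimate, lower, upper),
#'   `confusions` (named list of [confusion_matrix]), `c_statistics`
#'   (data frame: score, threshold_ml, c_statistic), and `overestimation`
#'   (data frame: method, pct).
#' @export
evaluate_cohort <- function(results, config = threshold_config(),
                            ci_level = 0.95,
                            ci_method = c("clopper-pearson", "wilson")) {
  ci_method <- match.arg(ci_method)
  needed <- c("od_value", "od_volume_ml", "abc2_volume_ml", "manual_volume_ml")
  if (!all(needed %in% names(results)))
    stop("`results` must contain columns: ", paste(needed, collapse = ", "))
  if (nrow(results) < 1L) stop("no evaluable patients")

  grid <- expand.grid(method = c("od_cutoff", "abc2"),
                      threshold_ml = c(70, 100), stringsAsFactors = FALSE)
  confusions <- list()
  metrics <- lapply(seq_len(nrow(grid)), function(i) {
    method <- grid$method[i]; thr <- grid$threshold_ml[i]
    label <- if (thr == 70) "70ml" else "100ml"
    pred <- classify_large_lesion(results, config, method, label)
    tru <- truth_label(results$manual_volume_ml, thr)
    cm <- confusion(pred, tru)
    confusions[[paste(method, label, sep = "_")]] <<- cm
    bm <- binary_metrics(cm, ci_level, ci_method)
    cbind(method = method, threshold_ml = thr, bm)
  })
  metrics <- do.call(rbind, metrics)

  scores <- list(od_volume = results$od_volume_ml,
                 abc2_volume = results$abc2_volume_ml)
  cs <- expand.grid(score = names(scores), threshold_ml = c(70, 100),
                    stringsAsFactors = FALSE)
  cs$c_statistic <- vapply(seq_len(nrow(cs)), function(i)
    c_statistic(scores[[cs$score[i]]],
                truth_label(results$manual_volume_ml, cs$threshold_ml[i])),
    numeric(1))

  over <- data.frame(
    method = c("od_volume", "abc2"),
    pct = c(median_overestimation(results$od_volume_ml, results$manual_volume_ml),
            median_overestimation(results$abc2_volume_ml, results$manual_volume_ml)),
    stringsAsFactors = FALSE
  )

  structure(
    list(metrics = metrics, confusions = confusions, c_statistics = cs,
         overestimation = over, ci_level = ci_level, ci_method = ci_method),
    class = "cohort_evaluation"
  )
}

#' @export
print.cohort_evaluation <- function(x, ...) {
  cat("<cohort_evaluation>\n")
  wide <- x$metrics
  wide$cell <- sprintf("%.1f (%.1f-%.1f)", 100 * wide$estimate,
                       100 * wide$lower, 100 * wide$upper)
  tab <- stats::reshape(
    wide[, c("method", "threshold_ml", "metric", "cell")],
    idvar = c("method", "threshold_ml"), timevar = "metric",
    direction = "wide"
  )
  names(tab) <- sub("^cell\\.", "", names(tab))
  print(tab, row.names = FALSE)
  cat("\nC-statistics:\n")
  print(x$c_statistics, row.names = FALSE)
  cat("\nMedian-volume overestimation (%):\n")
  print(x$overestimation, row.names = FALSE)
  invisible(x)
}
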