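#' Empirical ROC curve with DeLong inference
#'
#' Operating points over all observed score thresholds under the rule
#' "positive <=> score > threshold", trapezoidal AUC (equal to the
#' tie-corrected Mann-Whitney statistic), and a DeLong 95% CI with a
#' two-sided p-value against AUC = 0.5.
#'
#' @param scores numeric decision scores (higher = more malignant).
#' @param labels `"benign"`/`"malignant"` (or logical malignant).
#' @return object of class `roc_result`: `points` (threshold, sensitivity,
#'   specificity), `auc`, `auc_ci`, `p_value`, `n_pos`, `n_neg`.
#' @export
roc_curve <- function(scores, labels) {
  pos <- if (is.logical(labels)) labels else labels == "malignant"
  if (!any(pos) || all(pos)) stop("both classes must be present")
  thr <- c(-Inf, sort(unique(scores)))
  sens <- vapply(thr, function(t) mean(scores[pos] > t), numeric(1))
  spec <- vapply(thr, function(t) mean(scores[!pos] <= t), numeric(1))
  # trapezoid over (FPR, TPR)
  fpr <- 1 - spec
  o <- order(fpr, sens)
  auc <- sum(diff(fpr[o]) * (utils::head(sens[o], -1) + utils::tail(sens[o], -1)) / 2)
  auc <- abs(auc)
  r <- pROC::roc(response = pos, predictor = scores, quiet = TRUE,
                 direction = "<", levels = c(FALSE, TRUE))
  v <- suppressWarnings(pROC::var(r, method = "delong"))
  ci <- suppressWarnings(as.numeric(pROC::ci.auc(r, method = "delong"))[c(1, 3)])
  z <- (auc - 0.5) / sqrt(v)
  structure(list(points = data.frame(threshold = thr, sensitivity = sens,
                                     specificity = spec),
                 auc = auc, auc_ci = ci,
                 p_value = 2 * stats::pnorm(-abs(z)),
                 n_pos = sum(pos), n_neg = sum(!pos)),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("AUC %.1f%% (95%% CI %.1f-%.1f%%), p = %.3g; %d malignant / %d benign\n",
              100 * x$auc, 100 * x$auc_ci[1], 100 * x$auc_ci[2],
              x$p_value, x$n_pos, x$n_neg))
  invisible(x)
}

#' High-sensitivity operating cutoff
#'
#' Among all candidate thresholds (the observed scores plus -Inf), returns
#' the one maximizing specificity subject to sensitivity >= the requested
#' minimum under the rule "positive <=> score > threshold"; ties go to the
#' larger threshold. The constraint is always satisfiable (threshold -Inf
#' classifies everything positive).
#'
#' @param scores training decision scores.
#' @param labels training labels.
#' @param min_sensitivity required sensitivity in (0, 1].
#' @return the threshold (named, with achieved training sensitivity and
#'   specificity as attributes).
#' @export
find_sensitivity_cutoff <- function(scores, labels, min_sensitivity = 1.0) {
  if (min_sensitivity <= 0 || min_sensitivity > 1)
    stop("min_sensitivity must lie in (0, 1]")
  pos <- if (is.logical(labels)) labels else labels == "malignant"
  thr <- c(-Inf, sort(unique(scores)))
  sens <- vapply(thr, function(t) mean(scores[pos] > t), numeric(1))
  spec <- vapply(thr, function(t) mean(scores[!pos] <= t), numeric(1))
  feas <- sens >= min_sensitivity
  best_spec <- max(spec[feas])
  cand <- thr[feas & spec == best_spec]
  out <- max(cand)
  attr(out, "sensitivity") <- sens[thr == out & feas][1]
  attr(out, "specificity") <- best_spec
  out
}

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' @param successes,n counts, `0 <= successes <= n`.
#' @param level confidence level (default 0.95).
#' @return c(lower, upper) on the proportion scale; `x = 0` gives lower 0,
#'   `x = n` gives upper 1 and lower `(alpha/2)^(1/n)`.
#' @export
clopper_pearson <- function(successes, n, level = 0.95) {
  if (n < 1 || successes < 0 || successes > n || successes != round(successes))
    stop("invalid counts")
  a <- 1 - level
  lo <- if (successes == 0) 0 else stats::qbeta(a / 2, successes, n - successes + 1)
  hi <- if (successes == n) 1 else stats::qbeta(1 - a / 2, successes + 1, n - successes)
  c(lower = lo, upper = hi)
}

#' Wilson score interval
#'
#' @inheritParams clopper_pearson
#' @return c(lower, upper).
#' @export
wilson_interval <- function(successes, n, level = 0.95) {
  if (n < 1 || successes < 0 || successes > n) stop("invalid counts")
  z <- stats::qnorm(1 - (1 - level) / 2)
  p <- successes / n
  den <- 1 + z^2 / n
  mid <- p + z^2 / (2 * n)
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))
  c(lower = (mid - half) / den, upper = (mid + half) / den)
}

#' Diagnostic metrics from a 2x2 contingency table
#'
#' Sensitivity, specificity, PPV, NPV, accuracy (with 95% CIs) and the
#' positive/negative likelihood ratios from the four counts. The avoidable
#' biopsy fraction equals the specificity: in a population consisting only
#' of biopsied suspicious findings, every benign lesion classified below
#' the cutoff is a biopsy that could have been avoided.
#'
#' @param tp,fp,tn,fn nonnegative integer counts; `tp + fn >= 1` and
#'   `tn + fp >= 1`.
#' @param ci_method `"clopper-pearson"` (exact, default) or `"wilson"`.
#' @param level confidence level.
#' @return object of class `cutoff_report`: a list of proportions (0-1
#'   scale), their CIs, `plr`/`nlr` (Inf flagged via `plr_defined`), the
#'   counts, and `avoidable_biopsy_fraction`.
#' @examples
#' r <- contingency_metrics(tp = 88, fp = 59, tn = 10, fn = 0)
#' round(100 * r$specificity, 1)  # 14.5
#' @export
contingency_metrics <- function(tp, fp, tn, fn,
                                ci_method = c("clopper-pearson", "wilson"),
                                level = 0.95) {
  ci_method <- match.arg(ci_method)
  cts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(cts < 0) || any(cts != round(cts))) stop("counts must be nonnegative integers")
  if (tp + fn < 1 || tn + fp < 1) stop("need at least one lesion per class")
  ci <- if (ci_method == "wilson") wilson_interval else clopper_pearson
  total <- tp + fp + tn + fn
  prop <- function(x, n) list(est = x / n, ci = ci(x, n, level), x = x, n = n)
  sens <- prop(tp, tp + fn)
  spec <- prop(tn, tn + fp)
  ppv <- if (tp + fp >= 1) prop(tp, tp + fp) else NULL
  npv <- if (tn + fn >= 1) prop(tn, tn + fn) else NULL
  acc <- prop(tp + tn, total)
  plr_defined <- spec$est < 1
  nlr_defined <- spec$est > 0
  structure(list(
    counts = cts,
    sensitivity = sens$est, sensitivity_ci = sens$ci,
    specificity = spec$est, specificity_ci = spec$ci,
    ppv = if (is.null(ppv)) NA_real_ else ppv$est,
    ppv_ci = if (is.null(ppv)) c(NA, NA) else ppv$ci,
    npv = if (is.null(npv)) NA_real_ else npv$est,
    npv_ci = if (is.null(npv)) c(NA, NA) else npv$ci,
    accuracy = acc$est, accuracy_ci = acc$ci,
    plr = if (plr_defined) sens$est / (1 - spec$est) else Inf,
    plr_defined = plr_defined,
    nlr = if (nlr_defined) (1 - sens$est) / spec$est else Inf,
    nlr_defined = nlr_defined,
    avoidable_biopsy_fraction = spec$est,
    ci_method = ci_method),
    class = "cutoff_report")
}

#' @export
print.cutoff_report <- function(x, ...) {
  pct <- function(p, ci) sprintf("%.1f%% (95%% CI %.1f-%.1f%%)",
                                 100 * p, 100 * ci[1], 100 * ci[2])
  with(x, {
    cat(sprintf("counts TP=%d FP=%d TN=%d FN=%d\n",
                counts["tp"], counts["fp"], counts["tn"], counts["fn"]))
    cat(" sensitivity", pct(sensitivity, sensitivity_ci), "\n",
        "specificity", pct(specificity, specificity_ci),
        "(avoidable biopsies)\n",
        "PPV", pct(ppv, ppv_ci), " NPV", pct(npv, npv_ci), "\n",
        "accuracy", pct(accuracy, accuracy_ci), "\n",
        sprintf(" +LR %.1f  -LR %.1f\n", plr, nlr))
  })
  invisible(x)
}

#' Apply fixed high-sensitivity cutoffs to a held-out test set
#'
#' Applies thresholds fitted on the training set (rule: positive <=>
#' pseudo-probability > threshold) to untouched test scores, reporting the
#' full contingency metrics per cutoff and the false-negative lesion ids
#' for the malignancy audit.
#'
#' @param scores test pseudo-probabilities.
#' @param labels test labels.
#' @param thresholds named numeric vector of thresholds (e.g.
#'   `c(C1 = 0.17, C2 = 0.26)`).
#' @param lesion_ids optional ids for the false-negative audit.
#' @param ci_method passed to [contingency_metrics()].
#' @return named list of `cutoff_report`s, each carrying a
#'   `false_negative_ids` element.
#' @export
evaluate_cutoffs <- function(scores, labels, thresholds, lesion_ids = NULL,
                             ci_method = "clopper-pearson") {
  if (missing(thresholds) || is.null(thresholds) || !length(thresholds))
    stop("thresholds must be provided (fit them on the training set)")
  pos <- if (is.logical(labels)) labels else labels == "malignant"
  if (is.null(lesion_ids)) lesion_ids <- seq_along(scores)
  out <- lapply(thresholds, function(t) {
    pred <- scores > t
    cts <- c(tp = sum(pred & pos), fp = sum(pred & !pos),
             tn = sum(!pred & !pos), fn = sum(!pred & pos))
    if (cts["tp"] + cts["fn"] == 0 || cts["tn"] + cts["fp"] == 0) {
      # one class absent: class-conditional rates are not applicable
      rep <- structure(list(counts = cts,
                            sensitivity = NA_real_, specificity = NA_real_,
                            accuracy = (cts["tp"] + cts["tn"]) / length(scores),
                            note = "single-class input: rates not applicable"),
                       class = "cutoff_report_degenerate")
    } else {
      rep <- contingency_metrics(unname(cts["tp"]), unname(cts["fp"]),
                                 unname(cts["tn"]), unname(cts["fn"]),
                                 ci_method = ci_method)
    }
    rep$threshold <- t
    rep$false_negative_ids <- lesion_ids[!pred & pos]
    rep
  })
  names(out) <- names(thresholds)
  out
}

#' Benchmark contingency counts of the published clinical classifier
#'
#' The 2x2 counts reported for a 470-lesion clinical breast-MRI cohort
#' (313 training / 157 test lesions) at the two high-sensitivity cutoffs
#' C1 (training sensitivity 100%) and C2 (training sensitivity >= 95%),
#' together with the published display values they imply. Used to verify
#' that the package's contingency arithmetic reproduces the published
#' diagnostic table from its raw counts.
#'
#' @return data.frame: split, cutoff, tp, fp, tn, fn.
#' @export
benchmark_counts <- function() {
  data.frame(
    split = c("training", "training", "test", "test"),
    cutoff = c("C1", "C2", "C1", "C2"),
    tp = c(207L, 197L, 88L, 84L),
    fn = c(0L, 10L, 0L, 4L),
    tn = c(10L, 45L, 10L, 25L),
    fp = c(96L, 61L, 59L, 44L),
    stringsAsFactors = FALSE)
}

#' Recompute the published diagnostic table from its raw counts
#'
#' Derives sensitivity, specificity, their 95% CIs and likelihood ratios
#' for every row of [benchmark_counts()], plus PPV/NPV/accuracy for the
#' test rows, rounded to the published one-decimal display. Test-row CIs
#' use the exact Clopper-Pearson interval; training specificity rows are
#' additionally reported with the Wilson interval, which is the method the
#' published training CIs match.
#'
#' @return data.frame with one row per split x cutoff and display columns.
#' @export
reproduce_reference_metrics <- function() {
  b <- benchmark_counts()
  rows <- lapply(seq_len(nrow(b)), function(i) {
    m <- contingency_metrics(b$tp[i], b$fp[i], b$tn[i], b$fn[i])
    w <- contingency_metrics(b$tp[i], b$fp[i], b$tn[i], b$fn[i],
                             ci_method = "wilson")
    data.frame(
      split = b$split[i], cutoff = b$cutoff[i],
      sensitivity = round(100 * m$sensitivity, 1),
      sens_ci_lo = round(100 * m$sensitivity_ci[1], 1),
      sens_ci_hi = round(100 * m$sensitivity_ci[2], 1),
      specificity = round(100 * m$specificity, 1),
      spec_ci_lo = round(100 * m$specificity_ci[1], 1),
      spec_ci_hi = round(100 * m$specificity_ci[2], 1),
      spec_ci_lo_wilson = round(100 * w$specificity_ci[1], 1),
      spec_ci_hi_wilson = round(100 * w$specificity_ci[2], 1),
      ppv = round(100 * m$ppv, 1), npv = round(100 * m$npv, 1),
      accuracy = round(100 * m$accuracy, 1),
      plr = round(m$plr, 1), nlr = round(m$nlr, 1),
      avoidable_biopsy_pct = round(100 * m$avoidable_biopsy_fraction, 1),
      row.names = NULL)
  })
  do.call(rbind, rows)
}
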