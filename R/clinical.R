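#' One-way analysis of variance across diagnostic groups
#'
#' Classic equal-variance one-way ANOVA of a continuous baseline score
#' across diagnostic groups, as used to compare BrainAGE scores, cognitive
#' scores, hippocampus volumes or CSF levels between stable and progressive
#' MCI groups.
#'
#' @param data A data frame.
#' @param value,group Columns (unquoted) holding the score and the group
#'   label.
#' @return A one-row tibble with `statistic` (F), `df_between`, `df_within`,
#'   `p.value` and `degenerate` (`TRUE` when the within-group variance is
#'   zero and F is not finite).
#' @export
anova_oneway <- function(data, value, group) {
  v <- eval_tidy(enquo(value), data)
  g <- factor(eval_tidy(enquo(group), data))
  keep <- is.finite(v) & !is.na(g)
  v <- v[keep]; g <- droplevels(g[keep])
  if (nlevels(g) < 2L) abort("need at least 2 groups.")
  if (any(table(g) < 2L)) abort("each group needs at least 2 values.")
  fit <- stats::anova(stats::lm(v ~ g))
  ssw <- fit["Residuals", "Sum Sq"]
  ssb <- fit["g", "Sum Sq"]
  degenerate <- ssw <= 1e-12 * max(ssb + ssw, .Machine$double.eps)
  f <- if (degenerate) {
    if (ssb > 0) Inf else NaN
  } else {
    fit["g", "F value"]
  }
  if (degenerate) {
    warn("zero within-group variance: groups are exactly separated, F not finite.")
  }
  tibble::tibble(
    statistic = f,
    df_between = fit["g", "Df"], df_within = fit["Residuals", "Df"],
    p.value = if (degenerate) NA_real_ else fit["g", "Pr(>F)"],
    degenerate = degenerate
  )
}

#' Post-hoc pairwise Welch t-tests between groups
#'
#' Two-sample t-tests (Welch, unequal variances) for every pair of groups,
#' the usual follow-up to a significant one-way ANOVA.
#'
#' @inheritParams anova_oneway
#' @return A tibble with one row per group pair: `group1`, `group2`,
#'   `statistic`, `df`, `p.value`.
#' @export
posthoc_pairwise_t <- function(data, value, group) {
  v <- eval_tidy(enquo(value), data)
  g <- factor(eval_tidy(enquo(group), data))
  lv <- levels(droplevels(g))
  if (length(lv) < 2L) abort("need at least 2 groups.")
  pairs <- utils::combn(lv, 2, simplify = FALSE)
  purrr::map_dfr(pairs, function(p) {
    tt <- tryCatch(stats::t.test(v[g == p[1]], v[g == p[2]]),
                   error = function(e) NULL)
    tibble::tibble(
      group1 = p[1], group2 = p[2],
      statistic = if (is.null(tt)) NA_real_ else unname(tt$statistic),
      df = if (is.null(tt)) NA_real_ else unname(tt$parameter),
      p.value = if (is.null(tt)) NA_real_ else tt$p.value
    )
  })
}

#' Pearson correlation with two-sided p-value
#'
#' @param data A data frame.
#' @param x,y Columns (unquoted) to correlate.
#' @return A one-row tibble with `estimate` (r), `statistic` (t), `df`,
#'   `p.value`, `n`.
#' @export
pearson_cor <- function(data, x, y) {
  xv <- eval_tidy(enquo(x), data)
  yv <- eval_tidy(enquo(y), data)
  keep <- is.finite(xv) & is.finite(yv)
  xv <- xv[keep]; yv <- yv[keep]
  if (length(xv) < 3L) abort("need at least 3 complete pairs.")
  if (sd(xv) == 0 || sd(yv) == 0) abort("zero variance in `x` or `y`.")
  ct <- stats::cor.test(xv, yv, method = "pearson")
  tibble::tibble(estimate = unname(ct$estimate),
                 statistic = unname(ct$statistic),
                 df = unname(ct$parameter), p.value = ct$p.value,
                 n = length(xv))
}

# 2x2 classification table of predicted-positive (score above threshold,
# or below when direction = "<") against the true class.
confusion_counts <- function(scores, labels, threshold, direction) {
  pred <- if (direction == ">") scores > threshold else scores < threshold
  c(tp = sum(pred & labels), fp = sum(pred & !labels),
    fn = sum(!pred & labels), tn = sum(!pred & !labels))
}

wald_ci <- function(p, n, level = 0.95) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  half <- z * sqrt(p * (1 - p) / n)
  c(max(0, p - half), min(1, p + half))
}

#' Diagnostic performance at a threshold
#'
#' Accuracy, sensitivity and specificity of the rule "score above
#' `threshold` predicts the positive class" (below, when
#' `direction = "<"`), with 95% Wald confidence intervals. Denominators are
#' class-specific: accuracy over all subjects, sensitivity over positives,
#' specificity over negatives.
#'
#' @param data A data frame.
#' @param score,label Columns (unquoted): numeric score and logical (or
#'   two-level) true class, `TRUE` = positive (e.g. progressive MCI).
#' @param threshold Decision threshold on the score.
#' @param direction `">"` (default) if higher scores indicate the positive
#'   class, `"<"` otherwise.
#' @param level Confidence level for the Wald intervals.
#' @return A one-row tibble with the 2x2 counts, `accuracy`, `sensitivity`,
#'   `specificity`, `error_rate`, their CI bounds, and `degenerate`
#'   (`TRUE` when the threshold puts every subject on one side).
#' @export
performance_at_threshold <- function(data, score, label, threshold,
                                     direction = c(">", "<"), level = 0.95) {
  direction <- match.arg(direction)
  s <- eval_tidy(enquo(score), data)
  l <- as_binary_label(eval_tidy(enquo(label), data))
  if (!any(l) || all(l)) abort("both classes must be present.")
  cc <- confusion_counts(s, l, threshold, direction)
  n <- sum(cc); npos <- cc["tp"] + cc["fn"]; nneg <- cc["fp"] + cc["tn"]
  acc <- unname((cc["tp"] + cc["tn"]) / n)
  sens <- unname(cc["tp"] / npos)
  spec <- unname(cc["tn"] / nneg)
  ci_a <- wald_ci(acc, n, level)
  ci_s <- wald_ci(sens, npos, level)
  ci_p <- wald_ci(spec, nneg, level)
  degenerate <- (cc["tp"] + cc["fp"]) == 0 || (cc["fn"] + cc["tn"]) == 0
  if (degenerate) warn("degenerate 2x2 table: all predictions on one side.")
  tibble::tibble(
    threshold = threshold, direction = direction,
    tp = unname(cc["tp"]), fp = unname(cc["fp"]),
    fn = unname(cc["fn"]), tn = unname(cc["tn"]),
    accuracy = acc, accuracy_low = ci_a[1], accuracy_high = ci_a[2],
    sensitivity = sens, sensitivity_low = ci_s[1], sensitivity_high = ci_s[2],
    specificity = spec, specificity_low = ci_p[1], specificity_high = ci_p[2],
    error_rate = 1 - acc, error_rate_low = 1 - ci_a[2],
    error_rate_high = 1 - ci_a[1],
    degenerate = unname(degenerate)
  )
}

as_binary_label <- function(l) {
  if (is.logical(l)) return(l)
  f <- factor(l)
  if (nlevels(f) != 2L) abort("`label` must have exactly two classes.")
  f == levels(f)[2]
}

#' Choose the operating threshold on the ROC curve
#'
#' Scans every achievable operating point and returns the threshold
#' maximizing the given criterion (default: accuracy). Ties are broken
#' toward higher specificity (the more conservative rule), then toward the
#' larger threshold.
#'
#' @inheritParams performance_at_threshold
#' @param criterion Currently `"max_accuracy"`.
#' @return The selected threshold (a value such that "score > threshold"
#'   is the positive call under `direction = ">"`).
#' @export
select_threshold <- function(data, score, label, direction = c(">", "<"),
                             criterion = "max_accuracy") {
  direction <- match.arg(direction)
  criterion <- match.arg(criterion)
  s <- eval_tidy(enquo(score), data)
  l <- as_binary_label(eval_tidy(enquo(label), data))
  if (!any(l) || all(l)) abort("both classes must be present.")
  cand <- sort(unique(c(s, min(s) - 1)))
  stats_at <- t(vapply(cand, function(th) {
    cc <- confusion_counts(s, l, th, direction)
    c(acc = unname((cc["tp"] + cc["tn"]) / sum(cc)),
      spec = unname(cc["tn"] / (cc["fp"] + cc["tn"])))
  }, c(acc = 0, spec = 0)))
  best <- which(stats_at[, "acc"] == max(stats_at[, "acc"]))
  best <- best[stats_at[best, "spec"] == max(stats_at[best, "spec"])]
  cand[max(best)]
}

#' McNemar test for paired classifier comparison
#'
#' Compares two classifiers evaluated on the same subjects through their
#' discordant predictions: `b` subjects correctly classified by A but not
#' B, `c` the reverse. The statistic is `(b - c)^2 / (b + c)` against a
#' chi-squared distribution with 1 degree of freedom (uncorrected by
#' default; set `correct = TRUE` for the continuity-corrected variant).
#'
#' @param correct_a,correct_b Logical vectors, per-subject correctness of
#'   the two classifiers (paired, equal length).
#' @param correct Apply the continuity correction.
#' @return A one-row tibble with `b`, `c`, `statistic`, `p.value` and
#'   `note` (`"no discordance"` when `b + c = 0`, in which case the test is
#'   undefined and statistic/p are `NA`).
#' @export
mcnemar_test <- function(correct_a, correct_b, correct = FALSE) {
  if (length(correct_a) != length(correct_b)) {
    abort("paired inputs must have equal length.")
  }
  b <- sum(correct_a & !correct_b)
  cc <- sum(!correct_a & correct_b)
  if (b + cc == 0L) {
    return(tibble::tibble(b = b, c = cc, statistic = NA_real_,
                          p.value = NA_real_, note = "no discordance"))
  }
  num <- if (correct) (abs(b - cc) - 1)^2 else (b - cc)^2
  stat <- num / (b + cc)
  tibble::tibble(b = b, c = cc, statistic = stat,
                 p.value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
                 note = NA_character_)
}

#' Likelihood ratio and post-test probability
#'
#' Bayes update of the pre-test odds of conversion by the positive
#' likelihood ratio of a classifier: `LR+ = sensitivity / (1 -
#' specificity)`, post-test odds = pre-test odds x LR+, post-test
#' probability = odds / (1 + odds). The gain is the increase in probability
#' in percentage points.
#'
#' @param pre_positives,pre_negatives Pre-test counts (e.g. converters and
#'   non-converters in the sample); both > 0.
#' @param sensitivity,specificity Operating characteristics of the
#'   classifier, in (0, 1\]. `specificity = 1` yields an infinite LR+ and a
#'   post-test probability of 1.
#' @return A one-row tibble: `pre_test_probability`, `lr_positive`,
#'   `post_test_probability`, `gain` (percentage points).
#' @export
post_test <- function(pre_positives, pre_negatives, sensitivity, specificity) {
  stopifnot(pre_positives > 0, pre_negatives > 0,
            sensitivity > 0, sensitivity <= 1,
            specificity > 0, specificity <= 1)
  pre_odds <- pre_positives / pre_negatives
  pre_p <- pre_positives / (pre_positives + pre_negatives)
  if (specificity == 1) {
    lr <- Inf
    post_p <- 1
  } else {
    lr <- sensitivity / (1 - specificity)
    post_odds <- pre_odds * lr
    post_p <- post_odds / (1 + post_odds)
  }
  tibble::tibble(pre_test_probability = pre_p, lr_positive = lr,
                 post_test_probability = post_p,
                 gain = (post_p - pre_p) * 100)
}

#' Assign subjects to quartile groups of a score
#'
#' Quartile boundaries are the empirical 25th/50th/75th percentiles under
#' the linear-interpolation definition (`stats::quantile` type 7). Subjects
#' are assigned with left-closed intervals: a score equal to a boundary
#' falls in the upper quartile, so a score above the third boundary is
#' always in the fourth quartile.
#'
#' @param data A data frame.
#' @param score Column (unquoted) holding the score.
#' @param boundaries Optional length-3 numeric vector of externally fixed
#'   boundaries (25/50/75 cut points); computed from the data when `NULL`.
#' @param name Name of the new label column (default `"quartile"`).
#' @return `data` with an added ordered-factor column `Q1`-`Q4`, with the
#'   boundaries in `attr(, "boundaries")`. All-equal scores collapse to a
#'   single degenerate bin (`Q1`) with a warning.
#' @export
quartile_groups <- function(data, score, boundaries = NULL,
                            name = "quartile") {
  s <- eval_tidy(enquo(score), data)
  if (is.null(boundaries)) {
    if (length(s) < 4L) abort("need at least 4 scores for quartiles.")
    boundaries <- unname(quantile(s, c(0.25, 0.5, 0.75), type = 7))
  }
  if (length(unique(boundaries)) < 3L) {
    warn("degenerate quartiles: tied boundaries collapse bins.")
  }
  idx <- findInterval(s, boundaries) + 1L # left-closed: boundary -> upper bin
  lab <- factor(paste0("Q", idx), levels = paste0("Q", 1:4), ordered = TRUE)
  out <- dplyr::mutate(data, !!name := lab)
  attr(out, "boundaries") <- boundaries
  out
}
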