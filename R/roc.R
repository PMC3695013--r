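#' ROC curve and AUC
#'
#' Constructs the receiver operating characteristic by varying the decision
#' threshold over the observed scores. The area under the curve equals the
#' Mann-Whitney pair statistic: the probability that a random positive
#' subject scores above a random negative one, ties counting one half
#' (computed from midranks, so it is exact under ties).
#'
#' @param data A data frame.
#' @param score,label Columns (unquoted): numeric marker and true class
#'   (logical, `TRUE` = positive, or a two-level factor whose second level
#'   is positive).
#' @param direction `">"` (default) if higher scores indicate the positive
#'   class, `"<"` otherwise.
#' @return An object of class `brainage_roc`: a list with `points`
#'   (tibble of `threshold`, `sensitivity`, `specificity`, `fpr`), `auc`,
#'   `n_pos`, `n_neg`, `direction`.
#' @export
roc_curve <- function(data, score, label, direction = c(">", "<")) {
  direction <- match.arg(direction)
  s <- eval_tidy(enquo(score), data)
  l <- as_binary_label(eval_tidy(enquo(label), data))
  keep <- is.finite(s) & !is.na(l)
  s <- s[keep]; l <- l[keep]
  if (!any(l) || all(l)) abort("both classes must be present.")
  sx <- if (direction == ">") s else -s
  n_pos <- sum(l); n_neg <- sum(!l)
  r <- rank(sx) # midranks handle ties as half-successes
  auc <- (sum(r[l]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  th <- c(Inf, sort(unique(s), decreasing = (direction == ">")))
  pts <- purrr::map_dfr(th, function(t) {
    cc <- confusion_counts(s, l, if (is.infinite(t) && direction == "<") -Inf else t,
                           direction)
    tibble::tibble(threshold = t,
                   sensitivity = unname(cc["tp"] / n_pos),
                   specificity = unname(cc["tn"] / n_neg))
  })
  pts$fpr <- 1 - pts$specificity
  structure(list(points = pts, auc = auc, n_pos = n_pos, n_neg = n_neg,
                 direction = direction),
            class = "brainage_roc")
}

#' @export
print.brainage_roc <- function(x, ...) {
  cat(sprintf("<roc> AUC = %.4f (%d positives, %d negatives)\n",
              x$auc, x$n_pos, x$n_neg))
  invisible(x)
}

#' @export
glance.brainage_roc <- function(x, ...) {
  tibble::tibble(auc = x$auc, n_pos = x$n_pos, n_neg = x$n_neg,
                 direction = x$direction)
}

#' @export
tidy.brainage_roc <- function(x, ...) x$points

# DeLong placement values: for each positive, the fraction of negatives it
# beats (ties = 1/2); and symmetrically for negatives.
delong_placements <- function(s, l) {
  pos <- s[l]; neg <- s[!l]
  v10 <- vapply(pos, function(x) mean((x > neg) + 0.5 * (x == neg)), 0)
  v01 <- vapply(neg, function(y) mean((pos > y) + 0.5 * (pos == y)), 0)
  list(v10 = v10, v01 = v01, auc = mean(v10))
}

#' Paired comparison of two AUCs (DeLong)
#'
#' Tests whether marker A discriminates better than marker B on the same
#' subjects, using the DeLong covariance of the paired empirical AUCs. The
#' test is one-tailed by default (alternative: AUC of A greater than AUC of
#' B), matching the usual comparison of a new marker against established
#' ones.
#'
#' @param data A data frame.
#' @param score_a,score_b Columns (unquoted) with the two markers' scores.
#' @param label Column (unquoted) with the true class.
#' @param direction_a,direction_b Score direction per marker (see
#'   [roc_curve()]).
#' @param alternative `"greater"` (one-tailed, default), `"less"` or
#'   `"two.sided"`.
#' @return A one-row tibble: `auc_a`, `auc_b`, `delta`, `statistic` (z),
#'   `p.value`, `alternative`.
#' @export
compare_auc <- function(data, score_a, score_b, label,
                        direction_a = ">", direction_b = ">",
                        alternative = c("greater", "less", "two.sided")) {
  alternative <- match.arg(alternative)
  sa <- eval_tidy(enquo(score_a), data)
  sb <- eval_tidy(enquo(score_b), data)
  l <- as_binary_label(eval_tidy(enquo(label), data))
  if (length(sa) != length(sb) || length(sa) != length(l)) {
    abort("paired comparison requires the same subjects for both markers.")
  }
  if (!any(l) || all(l)) abort("both classes must be present.")
  if (direction_a == "<") sa <- -sa
  if (direction_b == "<") sb <- -sb
  pa <- delong_placements(sa, l)
  pb <- delong_placements(sb, l)
  m <- sum(l); n <- sum(!l)
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  var_delta <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
               (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  delta <- pa$auc - pb$auc
  z <- if (delta == 0) 0 else delta / sqrt(max(var_delta, .Machine$double.xmin))
  p <- switch(alternative,
              greater = stats::pnorm(z, lower.tail = FALSE),
              less = stats::pnorm(z),
              two.sided = 2 * stats::pnorm(-abs(z)))
  tibble::tibble(auc_a = pa$auc, auc_b = pb$auc, delta = delta,
                 statistic = z, p.value = p, alternative = alternative)
}
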