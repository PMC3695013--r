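test_that("one-way ANOVA matches the hand-computed F ratio", {
  d <- data.frame(v = c(1, 2, 3, 2, 3, 4, 3, 4, 5),
                  g = rep(c("a", "b", "c"), each = 3))
  out <- anova_oneway(d, v, g)
  # hand computation: SSB = 3*((2-3)^2+(3-3)^2+(4-3)^2) = 6, MSB = 3
  #                   SSW = 2+2+2 = 6, MSW = 1  ->  F = 3
  expect_equal(out$statistic, 3)
  expect_equal(out$df_between, 2)
  expect_equal(out$df_within, 6)

  same <- data.frame(v = c(1, 2, 3, 1, 2, 3), g = rep(c("a", "b"), each = 3))
  expect_equal(anova_oneway(same, v, g)$statistic, 0)
})

test_that("exactly separated zero-variance groups are flagged", {
  d <- data.frame(v = c(0, 0, 1, 1), g = rep(c("a", "b"), each = 2))
  out <- suppressWarnings(anova_oneway(d, v, g))
  expect_true(out$degenerate)
  expect_identical(out$statistic, Inf)
})

test_that("post-hoc Welch t-tests cover every pair of groups", {
  set.seed(51)
  d <- data.frame(v = c(rnorm(10), rnorm(10, 3), rnorm(10, 6)),
                  g = rep(c("a", "b", "c"), each = 10))
  out <- posthoc_pairwise_t(d, v, g)
  expect_equal(nrow(out), 3L)
  # oracle: direct Welch test on one pair
  tt <- t.test(d$v[d$g == "a"], d$v[d$g == "b"])
  expect_equal(out$p.value[out$group1 == "a" & out$group2 == "b"], tt$p.value)
})

test_that("pearson correlation matches hand arithmetic", {
  expect_equal(pearson_cor(data.frame(x = 1:5, y = 2 * (1:5)), x, y)$estimate, 1)
  expect_equal(pearson_cor(data.frame(x = 1:5, y = -(1:5)), x, y)$estimate, -1)
  # cov = 1/2, sd_x = 1, sd_y = 1  ->  r = 0.5
  expect_equal(pearson_cor(data.frame(x = 1:3, y = c(1, 3, 2)), x, y)$estimate,
               0.5)
  expect_error(pearson_cor(data.frame(x = 1:3, y = c(2, 2, 2)), x, y),
               "zero variance")
})

test_that("diagnostic performance reproduces the 2x2 table exactly", {
  d <- data.frame(score = c(1, 2, 3, 10, 11, 12),
                  conv = rep(c(FALSE, TRUE), each = 3))
  out <- performance_at_threshold(d, score, conv, threshold = 5)
  expect_equal(out$accuracy, 1)
  expect_equal(out$sensitivity, 1)
  expect_equal(out$specificity, 1)
  # self-consistency: proportions recompute from the returned counts
  expect_equal(out$accuracy, (out$tp + out$tn) / (out$tp + out$fp + out$fn + out$tn))
  expect_equal(out$sensitivity, out$tp / (out$tp + out$fn))
  expect_equal(out$specificity, out$tn / (out$fp + out$tn))

  all_pos <- suppressWarnings(
    performance_at_threshold(d, score, conv, threshold = 0))
  expect_equal(all_pos$sensitivity, 1)
  expect_equal(all_pos$specificity, 0)
  expect_true(all_pos$degenerate)
})

test_that("Wald confidence interval reproduces the printed-table arithmetic", {
  # accuracy 0.81 at n = 120 -> 0.81 +/- 1.96 * sqrt(.81*.19/120)
  ci <- c(0.81 - qnorm(0.975) * sqrt(0.81 * 0.19 / 120),
          0.81 + qnorm(0.975) * sqrt(0.81 * 0.19 / 120))
  expect_equal(round(ci, 2), c(0.74, 0.88))
  # same numbers through the package path (97/120 correct)
  d <- data.frame(
    score = c(rep(1, 85), rep(-1, 12), rep(-1, 12), rep(1, 11)),
    conv = c(rep(TRUE, 97), rep(FALSE, 23)))
  out <- performance_at_threshold(d, score, conv, 0)
  n <- 120; p <- out$accuracy
  expect_equal(round(c(out$accuracy_low, out$accuracy_high), 2),
               c(0.74, 0.88))
  expect_equal(out$accuracy_low, max(0, p - qnorm(0.975) * sqrt(p * (1 - p) / n)))
})

test_that("the max-accuracy threshold breaks ties toward specificity", {
  d <- data.frame(score = c(1, 2, 3, 4), conv = c(FALSE, FALSE, TRUE, TRUE))
  th <- select_threshold(d, score, conv)
  expect_true(th >= 2 && th < 3)
  perf <- performance_at_threshold(d, score, conv, th)
  expect_equal(perf$accuracy, 1)
  # with an unavoidable error, prefer the operating point with higher
  # specificity among equally accurate ones
  d2 <- data.frame(score = c(1, 3, 2, 4), conv = c(FALSE, FALSE, TRUE, TRUE))
  th2 <- select_threshold(d2, score, conv)
  p2 <- performance_at_threshold(d2, score, conv, th2)
  expect_gte(p2$specificity, p2$sensitivity)
})

test_that("McNemar statistic follows the discordant-pair formula", {
  # b = c = 5: no asymmetry
  a <- c(rep(TRUE, 5), rep(FALSE, 5), TRUE)
  b <- c(rep(FALSE, 5), rep(TRUE, 5), TRUE)
  out <- mcnemar_test(a, b)
  expect_equal(out$statistic, 0)
  expect_equal(out$p.value, 1)

  # b = 10, c = 2 -> (10-2)^2 / 12
  a2 <- c(rep(TRUE, 10), rep(FALSE, 2), rep(TRUE, 3))
  b2 <- c(rep(FALSE, 10), rep(TRUE, 2), rep(TRUE, 3))
  out2 <- mcnemar_test(a2, b2)
  expect_equal(out2$statistic, 64 / 12)
  # independent oracle: stats::mcnemar.test on the paired table
  tab <- table(factor(a2, c(FALSE, TRUE)), factor(b2, c(FALSE, TRUE)))
  expect_equal(out2$statistic,
               unname(stats::mcnemar.test(tab, correct = FALSE)$statistic))
  expect_equal(mcnemar_test(a2, b2, correct = TRUE)$statistic,
               unname(stats::mcnemar.test(tab, correct = TRUE)$statistic))

  same <- mcnemar_test(a, a)
  expect_identical(same$note, "no discordance")
  expect_true(is.na(same$statistic))
})

test_that("post-test probability follows likelihood-ratio algebra", {
  # printed whole-sample counts and BrainAGE operating characteristics
  out <- post_test(133, 62, 0.71, 0.84)
  expect_equal(round(100 * out$post_test_probability), 90)
  expect_equal(round(out$gain), 22)

  # LR+ = 1 leaves the probability unchanged
  nil <- post_test(50, 50, 0.3, 0.7)
  expect_equal(nil$post_test_probability, nil$pre_test_probability)

  # CSF-subsample counts with the matching operating characteristics
  csf <- post_test(66, 33, 0.67, 0.82)
  expect_equal(round(csf$gain), 21)

  # perfect specificity: infinite LR+, certainty
  perf <- post_test(10, 10, 0.8, 1)
  expect_identical(perf$lr_positive, Inf)
  expect_equal(perf$post_test_probability, 1)
})

test_that("post-test probability is monotone in sensitivity", {
  sens <- seq(0.05, 1, by = 0.05)
  post <- vapply(sens,
                 function(s) post_test(60, 40, s, 0.8)$post_test_probability,
                 0)
  expect_true(all(diff(post) >= 0))
})

test_that("quartile assignment uses interpolated boundaries, left-closed", {
  d <- data.frame(s = 1:8)
  q <- quartile_groups(d, s)
  expect_equal(attr(q, "boundaries"), c(2.75, 4.5, 6.25))
  expect_equal(as.character(q$quartile),
               c("Q1", "Q1", "Q2", "Q2", "Q3", "Q3", "Q4", "Q4"))

  # externally fixed boundaries: a score of 10 above the third cut is Q4
  ext <- quartile_groups(data.frame(s = 10), s,
                         boundaries = c(-0.12, 4.45, 9.26))
  expect_equal(as.character(ext$quartile), "Q4")

  expect_warning(quartile_groups(data.frame(s = rep(2, 8)), s), "degenerate")
})
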