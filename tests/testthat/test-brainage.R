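# Shared small noiseless cohort: the generative model is exactly linear in
# effective age, so the trained model must essentially invert it.
noiseless <- NULL
get_noiseless <- function() {
  if (is.null(noiseless)) {
    noiseless <<- run_small_pipeline(
      small_synth_config(delta_sd = 0, noise_sd = 0))
  }
  noiseless
}

test_that("a noiseless linear cohort is inverted almost exactly", {
  pipe <- get_noiseless()
  expect_lt(mean_absolute_error(pipe$eval_results), 0.1)
  # training subjects score ~0 too (interpolation of the generative model)
  tr <- pipe$sim$cohort[pipe$sim$cohort$role == "train", ][1:5, ]
  fx <- extract_features(pipe$sim$volumes[tr$subject_id],
                         mask = pipe$features$mask)
  res <- estimate_brain_age(
    pipe$estimator, fx$features,
    data.frame(subject_id = tr$subject_id, sex = tr$sex,
               age = tr$chronological_age))
  expect_lt(max(abs(res$brainage_score)), 0.1)
})

test_that("training is deterministic down to the serialized archive", {
  cfg <- small_synth_config(delta_sd = 0, noise_sd = 0)
  sim <- simulate_cohort(cfg)
  tr <- sim$cohort[sim$cohort$role == "train", ]
  fx <- extract_features(sim$volumes[tr$subject_id])
  info <- data.frame(subject_id = tr$subject_id, sex = tr$sex,
                     age = tr$chronological_age)
  e1 <- train_brainage(fx$features, info)
  e2 <- train_brainage(fx$features, info)
  expect_identical(serialize(e1, NULL), serialize(e2, NULL))
})

test_that("sex strata are trained and scored independently", {
  pipe <- get_noiseless()
  sim <- pipe$sim
  tr <- sim$cohort[sim$cohort$role == "train", ]
  fx <- pipe$features
  males <- tr$sex == "male"
  est_m <- train_brainage(
    fx$features[males, , drop = FALSE],
    data.frame(subject_id = tr$subject_id[males], sex = tr$sex[males],
               age = tr$chronological_age[males]),
    allow_single_sex = TRUE)
  ev <- sim$cohort[sim$cohort$role == "eval" & sim$cohort$sex == "male", ]
  fxe <- extract_features(sim$volumes[ev$subject_id], mask = fx$mask)
  info_e <- data.frame(subject_id = ev$subject_id, sex = ev$sex,
                       age = ev$chronological_age)
  from_male_only <- estimate_brain_age(est_m, fxe$features, info_e)
  from_both <- estimate_brain_age(pipe$estimator, fxe$features, info_e)
  expect_equal(from_male_only$estimated_age, from_both$estimated_age,
               tolerance = 1e-10)
})

test_that("stratum and input validation errors are explicit", {
  set.seed(41)
  X <- matrix(runif(5 * 20), 5, 20)
  rownames(X) <- paste0("s", 1:5)
  info <- data.frame(subject_id = rownames(X),
                     sex = c("male", "male", "male", "male", "female"),
                     age = c(60, 65, 70, 75, 80))
  expect_error(train_brainage(X, info), "stratum too small")
  info2 <- info; info2$sex <- "male"
  expect_error(train_brainage(X, info2), "single-sex")
  est <- train_brainage(X, info2, allow_single_sex = TRUE)
  expect_error(
    estimate_brain_age(est, X[1, , drop = FALSE],
                       data.frame(subject_id = "s1", sex = "female",
                                  age = 60)),
    "no trained model for sex")
  expect_error(
    estimate_brain_age(est, X[1, 1:10, drop = FALSE],
                       data.frame(subject_id = "s1", sex = "male", age = 60)),
    "feature length")
})

test_that("a mask mismatch between training and scoring is caught", {
  pipe <- get_noiseless()
  ev <- pipe$sim$cohort[pipe$sim$cohort$role == "eval", ][1:2, ]
  fxe <- extract_features(pipe$sim$volumes[ev$subject_id],
                          mask = pipe$features$mask)
  expect_error(
    estimate_brain_age(pipe$estimator, fxe$features,
                       data.frame(subject_id = ev$subject_id, sex = ev$sex,
                                  age = ev$chronological_age),
                       mask_checksum = "not-the-training-mask"),
    "preprocessing mismatch")
})

test_that("the BrainAGE score is exactly estimated minus chronological age", {
  pipe <- get_noiseless()
  res <- pipe$mci_results
  expect_identical(res$brainage_score,
                   res$estimated_age - res$chronological_age)
  # an estimated age of 75 at chronological 70 scores +5
  row <- tibble::tibble(estimated_age = 75, chronological_age = 70)
  expect_identical(row$estimated_age - row$chronological_age, 5)
})

test_that("MAE is the mean absolute BrainAGE score", {
  expect_equal(mean_absolute_error(data.frame(brainage_score = c(5, -5))), 5)
  expect_equal(mean_absolute_error(data.frame(brainage_score = rep(0, 4))), 0)
  expect_equal(mean_absolute_error(data.frame(brainage_score = c(1, 2, 6))), 3)
  expect_error(mean_absolute_error(data.frame(brainage_score = numeric(0))),
               "at least one")
})

test_that("estimator archives round-trip through disk", {
  pipe <- get_noiseless()
  path <- withr::local_tempfile(fileext = ".rds")
  save_brainage(pipe$estimator, path)
  back <- load_brainage(path)
  expect_identical(serialize(back, NULL), serialize(pipe$estimator, NULL))
  td <- tidy(pipe$estimator)
  expect_setequal(td$sex, c("male", "female"))
  expect_true(all(td$converged))
  expect_equal(glance(pipe$estimator)$n_strata, 2L)
})
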