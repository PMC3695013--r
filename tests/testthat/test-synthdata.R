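test_that("templates are deterministic with decline inside the head", {
  cfg <- small_synth_config()
  t1 <- make_template(cfg)
  t2 <- make_template(cfg)
  expect_identical(t1$baseline$data, t2$baseline$data)
  expect_identical(t1$decline$data, t2$decline$data)
  expect_true(all(t1$decline$data[!t1$support] == 0))
})

test_that("the configured decline fraction is achieved", {
  cfg <- small_synth_config(decline_fraction = 0.2)
  tpl <- make_template(cfg)
  achieved <- sum(tpl$decline$data > 0) / sum(tpl$support)
  expect_lt(abs(achieved - 0.2), 0.02)
})

test_that("gray matter declines monotonically with effective age", {
  cfg <- small_synth_config(noise_sd = 0)
  tpl <- make_template(cfg)
  v1 <- simulate_subject(tpl, 60, 0, "female", cfg, seed = 1)
  v2 <- simulate_subject(tpl, 80, 0, "female", cfg, seed = 1)
  dec <- tpl$decline$data > 0
  expect_true(all(v2$data[dec] <= v1$data[dec]))
  expect_identical(v1$data[!dec], v2$data[!dec])
})

test_that("the noiseless generative rule is the exact plug-in identity", {
  cfg <- small_synth_config(noise_sd = 0)
  tpl <- make_template(cfg)
  age <- 70; delta <- 6
  v <- simulate_subject(tpl, age, delta, "male", cfg, seed = 9)
  expected <- pmin(pmax(
    tpl$baseline$data -
      tpl$decline$data * cfg$sex_slope_factor[["male"]] * (age + delta - 50),
    0), 1)
  expect_equal(v$data, expected, tolerance = 1e-12)
})

test_that("subject simulation is bit-reproducible and range-checked", {
  cfg <- small_synth_config()
  tpl <- make_template(cfg)
  a <- simulate_subject(tpl, 70, 3, "female", cfg, seed = 77)
  b <- simulate_subject(tpl, 70, 3, "female", cfg, seed = 77)
  expect_identical(a$data, b$data)
  expect_error(simulate_subject(tpl, 130, 0, "male", cfg, seed = 1),
               "validity")
})

test_that("with beta = 0 conversion times are independent of the offset", {
  cfg <- synth_config(beta = 0, seed = 5,
                      n_train_male = 2L, n_train_female = 2L,
                      n_eval_male = 0L, n_eval_female = 0L,
                      group_sizes = c(sMCI = 170L, pMCI_late = 170L,
                                      pMCI_early = 160L))
  sim <- simulate_cohort(cfg, volumes = FALSE)
  tr <- sim$truth[!is.na(sim$truth$group_assigned), ]
  expect_lt(abs(cor(tr$conversion_time_raw, tr$delta)), 0.1)
})

test_that("assigned components carry the configured offsets", {
  cfg <- synth_config(seed = 8, n_train_male = 2L, n_train_female = 2L,
                      n_eval_male = 0L, n_eval_female = 0L)
  sim <- simulate_cohort(cfg, volumes = FALSE)
  tr <- merge(sim$truth, sim$cohort[, c("subject_id", "group")],
              by = "subject_id")
  tr <- tr[!is.na(tr$group_assigned), ]
  means <- tapply(tr$delta, tr$group_assigned, mean)
  for (g in names(cfg$group_deltas)) {
    expect_lt(abs(means[[g]] - cfg$group_deltas[[g]]), 0.5)
  }
  # derived clinical labels are consistent with the realized times
  mci <- sim$cohort[sim$cohort$role == "mci", ]
  expect_true(all(mci$group[mci$event & mci$time_to_event_days <= 365] ==
                    "pMCI_early"))
  expect_true(all(mci$group[!mci$event] == "sMCI"))
  expect_true(all(mci$time_to_event_days[!mci$event] == cfg$censor_days))
})

test_that("cohort simulation is reproducible and mirrors printed fractions", {
  cfg <- synth_config(seed = 12, n_train_male = 2L, n_train_female = 2L,
                      n_eval_male = 0L, n_eval_female = 0L)
  s1 <- simulate_cohort(cfg, volumes = FALSE)
  s2 <- simulate_cohort(cfg, volumes = FALSE)
  expect_identical(rlang::hash(s1$cohort), rlang::hash(s2$cohort))
  expect_identical(rlang::hash(s1$truth), rlang::hash(s2$truth))

  mci <- s1$cohort[s1$cohort$role == "mci", ]
  # conversion fractions in the ballpark of the emulated cohort
  expect_gt(mean(mci$event), 0.5); expect_lt(mean(mci$event), 0.85)
})

test_that("volumes and tables can be written to disk together", {
  cfg <- small_synth_config(
    n_train_male = 2L, n_train_female = 2L, n_eval_male = 0L,
    n_eval_female = 0L,
    group_sizes = c(sMCI = 2L, pMCI_late = 2L, pMCI_early = 2L))
  out <- withr::local_tempdir()
  sim <- simulate_cohort(cfg, write_dir = out)
  expect_true(file.exists(file.path(out, "cohort.tsv")))
  expect_true(file.exists(file.path(out, "cohort_truth.tsv")))
  expect_length(list.files(file.path(out, "volumes"), pattern = "nii"),
                nrow(sim$cohort))
  # truth lives in a separately named file, not in the cohort table
  cohort_cols <- names(read_cohort(file.path(out, "cohort.tsv")))
  expect_false(any(c("delta", "group_assigned") %in% cohort_cols))
})

test_that("invalid configurations are rejected up front", {
  expect_error(synth_config(noise_sd = -1), "noise_sd")
  expect_error(synth_config(censor_days = 0), "censor_days")
  expect_error(synth_config(group_deltas = c(a = 1, b = 2, c = 3)),
               "group names")
})
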