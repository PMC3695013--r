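#' Configuration of the synthetic gray-matter cohort generator
#'
#' The generator emulates the statistical structure the brain-age framework
#' assumes: a healthy training sample (ages ~51-94) whose gray-matter
#' density declines smoothly and linearly with age over a contiguous
#' "atrophy" region, a held-out healthy evaluation sample, and an MCI test
#' sample whose subjects carry a brain-age offset delta (years) drawn
#' around group-specific means, with conversion-to-AD times whose hazard
#' increases multiplicatively with delta.
#'
#' Defaults mirror the study conditions the framework was evaluated under:
#' 320 healthy training subjects (107 male / 213 female, ages 51-94), 64
#' held-out healthy subjects, three MCI groups of 60 with mean offsets
#' 0.75 / 5.62 / 8.73 years (stable, late and early converters), a hazard
#' of conversion increasing by 10% per offset year (`beta = log(1.10)`),
#' and censoring at 1095 days. `lambda0 = 7e-4`/day makes roughly 68% of
#' the MCI sample convert within 3 years and 30% within the first year.
#'
#' @param dim Grid dimensions (default `c(32, 40, 32)`).
#' @param spacing_mm Isotropic voxel size of the simulated volumes (mm).
#' @param n_train_male,n_train_female Healthy training stratum sizes.
#' @param n_eval_male,n_eval_female Healthy held-out evaluation sizes.
#' @param train_age_range,mci_age_range Uniform age ranges (years).
#' @param group_sizes Named sizes of the MCI delta-mixture components
#'   (`sMCI`, `pMCI_late`, `pMCI_early`).
#' @param group_deltas Named mean brain-age offsets (years) per component.
#' @param delta_sd Between-subject SD of the offset (years), all subjects.
#' @param noise_sd SD of the spatially smoothed gray-matter measurement
#'   noise (density units).
#' @param noise_fwhm_mm Correlation length (FWHM) of the noise field.
#' @param decline_fraction Fraction of head-support voxels with an age
#'   slope.
#' @param slope_range Range of the decline slope (density per year).
#' @param sex_slope_factor Multiplicative sex effect on the decline map.
#' @param baseline_peak Peak gray-matter density of the template.
#' @param lambda0 Baseline conversion hazard (per day).
#' @param beta Log-hazard per offset year (default `log(1.10)`).
#' @param censor_days Administrative censoring of follow-up (days).
#' @param seed Master seed; all randomness flows from it through
#'   documented per-subject substreams.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(dim = c(32L, 40L, 32L), spacing_mm = 4,
                         n_train_male = 107L, n_train_female = 213L,
                         n_eval_male = 24L, n_eval_female = 40L,
                         train_age_range = c(51, 94),
                         mci_age_range = c(55, 88),
                         group_sizes = c(sMCI = 60L, pMCI_late = 60L,
                                         pMCI_early = 60L),
                         group_deltas = c(sMCI = 0.75, pMCI_late = 5.62,
                                          pMCI_early = 8.73),
                         delta_sd = 1.5, noise_sd = 0.04,
                         noise_fwhm_mm = 6, decline_fraction = 0.2,
                         slope_range = c(0.002, 0.004),
                         sex_slope_factor = c(male = 1.1, female = 0.9),
                         baseline_peak = 0.85, lambda0 = 7e-4,
                         beta = log(1.10), censor_days = 1095L,
                         seed = 1L) {
  # tolerate list-valued fields (e.g. read back from a YAML config)
  dim <- unlist(dim); train_age_range <- unlist(train_age_range)
  mci_age_range <- unlist(mci_age_range)
  group_sizes <- unlist(group_sizes); group_deltas <- unlist(group_deltas)
  slope_range <- unlist(slope_range)
  sex_slope_factor <- unlist(sex_slope_factor)
  cfg <- list(dim = as.integer(dim), spacing_mm = spacing_mm,
              n_train_male = n_train_male, n_train_female = n_train_female,
              n_eval_male = n_eval_male, n_eval_female = n_eval_female,
              train_age_range = train_age_range,
              mci_age_range = mci_age_range,
              group_sizes = group_sizes, group_deltas = group_deltas,
              delta_sd = delta_sd, noise_sd = noise_sd,
              noise_fwhm_mm = noise_fwhm_mm,
              decline_fraction = decline_fraction,
              slope_range = slope_range,
              sex_slope_factor = sex_slope_factor,
              baseline_peak = baseline_peak, lambda0 = lambda0,
              beta = beta, censor_days = censor_days, seed = seed)
  validate_synth_config(cfg)
  structure(cfg, class = "synth_config")
}

validate_synth_config <- function(cfg) {
  if (length(cfg$dim) != 3L || any(cfg$dim < 4L)) {
    abort("`dim` must be 3 grid sizes >= 4.")
  }
  sizes <- c(cfg$n_train_male, cfg$n_train_female, cfg$group_sizes)
  if (any(sizes < 0) || sum(cfg$group_sizes) < 1) {
    abort("cohort sizes must be positive.")
  }
  if (!setequal(names(cfg$group_sizes), names(cfg$group_deltas))) {
    abort("`group_sizes` and `group_deltas` must share the same group names.")
  }
  if (cfg$noise_sd < 0) abort("`noise_sd` must be >= 0.")
  if (cfg$censor_days <= 0) abort("`censor_days` must be positive.")
  if (cfg$delta_sd < 0) abort("`delta_sd` must be >= 0.")
  invisible(cfg)
}

#' Build the baseline and decline-rate template volumes
#'
#' The baseline is a smooth head-like gray-matter map: a logistic radial
#' falloff of peak density inside an ellipsoid, zero in the background. The
#' decline map assigns an age slope (density lost per year) to a contiguous
#' cluster of voxels inside the head support: the configured fraction of
#' support voxels nearest to an interior anchor point, with slopes drawn
#' uniformly from `slope_range`. Deterministic given `config$seed`.
#'
#' @param config A [synth_config()].
#' @return A list with `baseline` and `decline` ([gm_volume()]s),
#'   `support` (logical array) and `valid_age_range` for effective ages.
#' @export
make_template <- function(config = synth_config()) {
  d <- config$dim
  cx <- (d + 1) / 2
  ax <- lapply(1:3, function(i) (seq_len(d[i]) - cx[i]) / (0.42 * d[i]))
  r2 <- outer(outer(ax[[1]]^2, ax[[2]]^2, `+`), ax[[3]]^2, `+`)
  r <- sqrt(r2)
  baseline <- config$baseline_peak / (1 + exp((r - 1) / 0.1))
  baseline[baseline < 1e-3] <- 0
  support <- baseline > 0
  # contiguous decline cluster: the target number of support voxels
  # closest to an interior anchor (off-centre, mimicking focal atrophy)
  anchor <- cx + c(0, 0.12, -0.08) * d
  idx <- which(support, arr.ind = TRUE)
  dist2 <- (idx[, 1] - anchor[1])^2 + (idx[, 2] - anchor[2])^2 +
    (idx[, 3] - anchor[3])^2
  n_decline <- round(config$decline_fraction * sum(support))
  sel <- order(dist2)[seq_len(n_decline)]
  decline <- array(0, dim = d)
  slopes <- with_seed(config$seed,
                      runif(n_decline, config$slope_range[1],
                            config$slope_range[2]))
  decline[idx[sel, , drop = FALSE]] <- slopes
  list(
    baseline = gm_volume(baseline, config$spacing_mm, "template_baseline"),
    decline = gm_volume(decline, config$spacing_mm, "template_decline"),
    support = support,
    valid_age_range = c(30, 120)
  )
}

# Smoothed Gaussian noise field with exact target pointwise SD: white noise
# is convolved with the Gaussian kernel and the variance shrinkage factor
# (product over axes of sum of squared taps) is compensated analytically.
smooth_noise_field <- function(dim, spacing_mm, fwhm_mm, sd) {
  eps <- array(rnorm(prod(dim)), dim = dim)
  shrink <- 1
  for (axis in 1:3) {
    sigma <- fwhm_mm * FWHM_TO_SIGMA / spacing_mm
    r <- max(1L, ceiling(4 * sigma))
    taps <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
    taps <- taps / sum(taps)
    shrink <- shrink * sum(taps^2)
    op <- gaussian_band_matrix(dim[axis], sigma)
    eps <- apply_along_axis(eps, op, axis)
  }
  eps * sd / sqrt(shrink)
}

#' Simulate one subject's gray-matter volume
#'
#' Generative rule: `v(x) = clip01(b(x) - s(x) * f_sex * (age + delta - 50)
#' + eps(x))` where `b` is the baseline template, `s` the decline-rate map,
#' `f_sex` a small multiplicative sex effect, and `eps` spatially smoothed
#' Gaussian noise. The decline term is anchored at 50 years, the start of
#' the training age range. Bit-reproducible given `seed`.
#'
#' @param template A [make_template()] result.
#' @param age Chronological age in years.
#' @param delta Brain-age offset in years (0 for healthy aging).
#' @param sex `"male"` or `"female"`.
#' @param config The [synth_config()] used for the template.
#' @param seed Per-subject RNG seed.
#' @param subject_id Identifier for the resulting volume.
#' @return A [gm_volume()].
#' @export
simulate_subject <- function(template, age, delta, sex,
                             config = synth_config(), seed = 1L,
                             subject_id = "synthetic") {
  eff_age <- age + delta
  if (eff_age < template$valid_age_range[1] ||
      eff_age > template$valid_age_range[2]) {
    abort(sprintf("effective age %.1f outside template validity [%g, %g].",
                  eff_age, template$valid_age_range[1],
                  template$valid_age_range[2]))
  }
  f_sex <- unname(config$sex_slope_factor[[sex]])
  v <- template$baseline$data -
    template$decline$data * f_sex * (eff_age - 50)
  if (config$noise_sd > 0) {
    v <- v + with_seed(seed, smooth_noise_field(
      config$dim, config$spacing_mm, config$noise_fwhm_mm, config$noise_sd))
  }
  v <- pmin(pmax(v, 0), 1)
  gm_volume(v, config$spacing_mm, subject_id)
}

#' Simulate a full synthetic cohort
#'
#' Generates the healthy training and evaluation samples and the MCI test
#' sample. Each MCI subject is assigned to a delta-mixture component with
#' the configured sizes, draws an offset `delta ~ N(delta_group,
#' delta_sd)`, and draws a conversion time `T ~ Exponential(lambda0 *
#' exp(beta * delta))`, administratively censored at `censor_days`. The
#' clinical group label is then derived from the realized conversion time,
#' mirroring how MCI cohorts are labelled in practice: conversion within
#' 365 days is `pMCI_early`, conversion within the censoring horizon is
#' `pMCI_late`, otherwise `sMCI` (censored). The originally assigned
#' mixture component is recorded in the separate truth table (never in the
#' cohort table), together with the true offsets, so that recovery analyses
#' cannot accidentally consume truth.
#'
#' Cognitive scores (MMSE, CDR-SB, ADAS) and hippocampus volumes are
#' generated for MCI subjects as noisy linear correlates of the true
#' offset, so the comparative statistics layer has realistic comparator
#' markers.
#'
#' @param config A [synth_config()].
#' @param volumes Generate gray-matter volumes (set `FALSE` for
#'   table-only simulations of the survival layer).
#' @param write_dir Optional directory; when given, volumes are written as
#'   NIfTI files and the cohort/truth tables as tab-separated text.
#' @return A list with `cohort` (tibble), `truth` (tibble), `volumes`
#'   (named list of [gm_volume()] or `NULL`), `template`, `config`.
#' @export
simulate_cohort <- function(config = synth_config(), volumes = TRUE,
                            write_dir = NULL) {
  validate_synth_config(config)
  template <- make_template(config)
  groups <- names(config$group_sizes)
  n_mci <- sum(config$group_sizes)
  n_train <- config$n_train_male + config$n_train_female
  n_eval <- config$n_eval_male + config$n_eval_female
  n_all <- n_train + n_eval + n_mci

  role <- c(rep("train", n_train), rep("eval", n_eval), rep("mci", n_mci))
  sex <- c(rep("male", config$n_train_male),
           rep("female", config$n_train_female),
           rep("male", config$n_eval_male),
           rep("female", config$n_eval_female),
           rep(c("male", "female"), length.out = n_mci))
  assigned <- c(rep(NA_character_, n_train + n_eval),
                rep(groups, config$group_sizes))
  id <- sprintf("S%04d", seq_len(n_all))

  tabs <- with_seed(config$seed, {
    age <- numeric(n_all)
    age[role != "mci"] <- runif(n_train + n_eval, config$train_age_range[1],
                                config$train_age_range[2])
    age[role == "mci"] <- runif(n_mci, config$mci_age_range[1],
                                config$mci_age_range[2])
    delta <- rnorm(n_all, 0, config$delta_sd)
    delta[role == "mci"] <- delta[role == "mci"] +
      config$group_deltas[assigned[role == "mci"]]
    conv_raw <- rep(NA_real_, n_all)
    is_mci <- role == "mci"
    conv_raw[is_mci] <- rexp(n_mci, rate = config$lambda0 *
                               exp(config$beta * delta[is_mci]))
    education <- sample(10:20, n_all, replace = TRUE)
    mmse <- pmin(30, pmax(0, 27 - 0.25 * delta + rnorm(n_all, 0, 1.5)))
    cdr_sb <- pmin(18, pmax(0, 1.5 + 0.15 * delta + rnorm(n_all, 0, 0.8)))
    adas <- pmin(85, pmax(0, 10 + 0.6 * delta + rnorm(n_all, 0, 3)))
    hippo_l <- 3500 - 40 * delta + rnorm(n_all, 0, 250)
    hippo_r <- 3550 - 38 * delta + rnorm(n_all, 0, 250)
    list(age = age, delta = delta, conv_raw = conv_raw,
         education = education, mmse = mmse, cdr_sb = cdr_sb, adas = adas,
         hippo_l = hippo_l, hippo_r = hippo_r)
  })
  subject_seeds <- derive_seeds(config$seed + 1L, n_all)

  event <- !is.na(tabs$conv_raw) & tabs$conv_raw <= config$censor_days
  time_days <- ifelse(role == "mci",
                      ifelse(event, ceiling(tabs$conv_raw),
                             config$censor_days),
                      NA_real_)
  group <- rep(NA_character_, n_all)
  group[role == "mci"] <- ifelse(
    !event[role == "mci"], "sMCI",
    ifelse(time_days[role == "mci"] <= 365, "pMCI_early", "pMCI_late"))

  cohort <- tibble::tibble(
    subject_id = id, role = role, sex = sex,
    chronological_age = tabs$age, education_years = tabs$education,
    group = group, event = ifelse(role == "mci", event, NA),
    time_to_event_days = time_days,
    mmse = tabs$mmse, cdr_sb = tabs$cdr_sb, adas = tabs$adas,
    hippocampus_left = tabs$hippo_l, hippocampus_right = tabs$hippo_r
  )
  truth <- tibble::tibble(
    subject_id = id, delta = tabs$delta, group_assigned = assigned,
    conversion_time_raw = tabs$conv_raw, subject_seed = subject_seeds
  )

  vols <- NULL
  if (isTRUE(volumes)) {
    vols <- purrr::pmap(
      list(id, tabs$age, tabs$delta, sex, subject_seeds),
      function(sid, a, dl, sx, sd_i) {
        simulate_subject(template, a, dl, sx, config, seed = sd_i,
                         subject_id = sid)
      })
    names(vols) <- id
  }

  if (!is.null(write_dir)) {
    dir.create(write_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(cohort, file.path(write_dir, "cohort.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(truth, file.path(write_dir, "cohort_truth.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    if (!is.null(vols)) {
      vdir <- file.path(write_dir, "volumes")
      dir.create(vdir, showWarnings = FALSE)
      purrr::walk(vols, function(v) {
        write_gm_volume(v, file.path(vdir, paste0(v$subject_id, ".nii.gz")))
      })
    }
  }
  list(cohort = cohort, truth = truth, volumes = vols,
       template = template, config = config)
}
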