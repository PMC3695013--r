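#' Train the brain-age estimation model
#'
#' Trains, separately for male and female subjects, a principal-component
#' reduction of the gray-matter feature vectors followed by relevance
#' vector regression of chronological age on the component scores with a
#' linear (degree-1 polynomial) kernel. PCA is fitted on the training
#' stratum only and its parameters are frozen; test subjects are projected
#' with the stored transformation.
#'
#' @param features Numeric matrix of gray-matter features (subjects in
#'   rows; rownames must be subject ids), e.g. from [extract_features()].
#' @param info Data frame with columns `subject_id`, `sex`
#'   (`"male"`/`"female"`) and `age` (chronological age in years, > 0),
#'   one row per feature row.
#' @param kernel A [kernel_spec()]; default linear with bias.
#' @param rvr_control An [rvr_config()].
#' @param allow_single_sex Permit training with only one sex stratum
#'   (useful for small synthetic experiments; the production default
#'   requires both).
#' @param mask_checksum Optional checksum of the mask the features were
#'   extracted under (from [extract_features()]); stored and verified at
#'   prediction time.
#' @return An object of class `brainage_estimator`.
#' @export
train_brainage <- function(features, info, kernel = kernel_spec(),
                           rvr_control = rvr_config(),
                           allow_single_sex = FALSE,
                           mask_checksum = NULL) {
  info <- validate_subject_info(info, nrow(features))
  sexes <- unique(info$sex)
  if (length(sexes) < 2L && !allow_single_sex) {
    abort(paste0("only one sex stratum present ('", sexes, "'); ",
                 "set `allow_single_sex = TRUE` for single-sex training."))
  }
  counts <- table(info$sex)
  if (any(counts < 2L)) {
    abort(sprintf("sex stratum too small: %s has %d subject(s), need >= 2.",
                  names(counts)[which.min(counts)], min(counts)))
  }
  models <- lapply(sexes, function(s) {
    idx <- which(info$sex == s)
    pca <- fit_pca(features[idx, , drop = FALSE])
    scores <- apply_pca(pca, features[idx, , drop = FALSE])
    phi <- rvr_design(scores, scores, kernel)
    rvr <- fit_rvr(phi, info$age[idx], rvr_control)
    list(pca = pca, rvr = rvr, basis_scores = scores, n_train = length(idx))
  })
  names(models) <- sexes
  structure(
    list(models = models, kernel = kernel, rvr_control = rvr_control,
         n_features = ncol(features), mask_checksum = mask_checksum),
    class = "brainage_estimator"
  )
}

validate_subject_info <- function(info, n_rows) {
  info <- as.data.frame(info)
  req <- c("subject_id", "sex", "age")
  missing_cols <- setdiff(req, names(info))
  if (length(missing_cols)) {
    abort(paste0("`info` is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (!is.null(n_rows) && nrow(info) != n_rows) {
    abort("`info` must have one row per feature row.")
  }
  if (!all(info$sex %in% c("male", "female"))) {
    abort("`sex` must be 'male' or 'female' (stratified training requires it).")
  }
  if (any(!is.finite(info$age)) || any(info$age <= 0)) {
    abort("`age` must be positive and finite.")
  }
  info
}

#' Estimate brain age and the BrainAGE score
#'
#' Projects each test subject's gray-matter features through the sex-matched
#' frozen PCA and predicts age with the sex-matched relevance vector
#' regression. The BrainAGE score is the estimated minus the chronological
#' age, in years: a subject aged 70 with an estimated brain age of 75 has a
#' BrainAGE score of +5, i.e. the atrophy pattern typical of a 75-year-old.
#'
#' @param estimator A [train_brainage()] result.
#' @param features Feature matrix for the test subjects (same feature space
#'   as training; verified via the stored mask checksum when available).
#' @param info Data frame with `subject_id`, `sex`, `age` per feature row.
#' @param mask_checksum Optional checksum of the mask used for these
#'   features; must match the estimator's if both are present.
#' @return A tibble with columns `subject_id`, `sex`, `chronological_age`,
#'   `estimated_age`, `brainage_score` and `predictive_sd`.
#' @export
estimate_brain_age <- function(estimator, features, info,
                               mask_checksum = NULL) {
  stopifnot(inherits(estimator, "brainage_estimator"))
  if (is.null(dim(features))) features <- matrix(features, nrow = 1)
  info <- validate_subject_info(info, nrow(features))
  if (ncol(features) != estimator$n_features) {
    abort(sprintf("feature length %d does not match the estimator's %d.",
                  ncol(features), estimator$n_features))
  }
  if (!is.null(mask_checksum) && !is.null(estimator$mask_checksum) &&
      !identical(mask_checksum, estimator$mask_checksum)) {
    abort("preprocessing mismatch: feature mask differs from the training mask.")
  }
  est <- rep(NA_real_, nrow(features))
  psd <- rep(NA_real_, nrow(features))
  for (s in unique(info$sex)) {
    if (is.null(estimator$models[[s]])) {
      abort(sprintf("no trained model for sex '%s'.", s))
    }
    m <- estimator$models[[s]]
    idx <- which(info$sex == s)
    scores <- apply_pca(m$pca, features[idx, , drop = FALSE])
    phi <- rvr_design(scores, m$basis_scores, estimator$kernel)
    pred <- predict_rvr(m$rvr, phi)
    est[idx] <- pred$mean
    psd[idx] <- sqrt(pred$variance)
  }
  tibble::tibble(
    subject_id = info$subject_id,
    sex = info$sex,
    chronological_age = info$age,
    estimated_age = est,
    brainage_score = est - info$age,
    predictive_sd = psd
  )
}

#' Mean absolute error of brain-age estimates
#'
#' The mean of the absolute BrainAGE scores, in years; the standard
#' evaluation measure of brain-age frameworks on healthy hold-out samples.
#'
#' @param results A tibble from [estimate_brain_age()] (or any data frame
#'   with a `brainage_score` column).
#' @return MAE in years.
#' @export
mean_absolute_error <- function(results) {
  if (is.data.frame(results)) results <- results$brainage_score
  if (length(results) < 1L || is.null(results)) {
    abort("need at least one BrainAGE result.")
  }
  mean(abs(results))
}

#' @export
print.brainage_estimator <- function(x, ...) {
  cat(sprintf("<brainage_estimator> strata: %s; %d gray-matter features\n",
              paste(names(x$models), collapse = ", "), x$n_features))
  for (s in names(x$models)) {
    m <- x$models[[s]]
    cat(sprintf("  %s: n=%d, %d PCs, %d relevance vectors, sigma2=%.3g\n",
                s, m$n_train, m$pca$n_components,
                length(m$rvr$relevance_indices), m$rvr$sigma2))
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.brainage_estimator <- function(x, ...) {
  purrr::map_dfr(names(x$models), function(s) {
    m <- x$models[[s]]
    tibble::tibble(
      sex = s, n_train = m$n_train, n_components = m$pca$n_components,
      n_relevance_vectors = length(m$rvr$relevance_indices),
      noise_variance = m$rvr$sigma2, iterations = m$rvr$iterations,
      converged = m$rvr$converged
    )
  })
}

#' @export
glance.brainage_estimator <- function(x, ...) {
  tibble::tibble(
    n_strata = length(x$models),
    n_features = x$n_features,
    n_train = sum(vapply(x$models, function(m) m$n_train, 0)),
    kernel_degree = x$kernel$degree
  )
}

#' Save / load a brain-age estimator archive
#'
#' The archive bundles the per-sex PCA and RVR models, the kernel and
#' optimizer configuration, and the mask checksum, so a saved estimator can
#' score new subjects reproducibly.
#'
#' @param estimator A [train_brainage()] result.
#' @param path File path for the archive.
#' @return `path` (write) or the restored estimator (read).
#' @export
save_brainage <- function(estimator, path) {
  stopifnot(inherits(estimator, "brainage_estimator"))
  saveRDS(estimator, path, version = 2)
  invisible(path)
}

#' @rdname save_brainage
#' @export
load_brainage <- function(path) {
  est <- readRDS(path)
  if (!inherits(est, "brainage_estimator")) {
    abort(sprintf("'%s' is not a brain-age estimator archive.", path))
  }
  est
}
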