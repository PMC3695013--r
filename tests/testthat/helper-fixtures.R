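# Shared fixtures: everything is generated in code at test time.

# Small-grid generator configuration for fast pipeline tests.
small_synth_config <- function(..., seed = 42L) {
  args <- list(
    dim = c(16L, 20L, 16L), spacing_mm = 6,
    n_train_male = 30L, n_train_female = 30L,
    n_eval_male = 10L, n_eval_female = 10L,
    group_sizes = c(sMCI = 6L, pMCI_late = 6L, pMCI_early = 6L),
    seed = seed
  )
  overrides <- list(...)
  args[names(overrides)] <- overrides
  do.call(synth_config, args)
}

# A deterministic random gm_volume.
random_volume <- function(dim = c(12, 12, 12), spacing = 2, seed = 1,
                          id = "rand") {
  set.seed(seed)
  gm_volume(array(runif(prod(dim)), dim = dim), spacing, id)
}

# Exhaustive pair-counting AUC oracle (ties count one half).
auc_by_pairs <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  total <- 0
  for (p in pos) for (n in neg) {
    total <- total + (p > n) + 0.5 * (p == n)
  }
  total / (length(pos) * length(neg))
}

# Train/score a small synthetic cohort end to end; returns the pieces.
run_small_pipeline <- function(cfg) {
  sim <- simulate_cohort(cfg)
  coh <- sim$cohort
  tr <- coh[coh$role == "train", ]
  fx <- extract_features(sim$volumes[tr$subject_id])
  est <- train_brainage(
    fx$features,
    data.frame(subject_id = tr$subject_id, sex = tr$sex,
               age = tr$chronological_age),
    mask_checksum = fx$mask_checksum
  )
  score_role <- function(role) {
    part <- coh[coh$role == role, ]
    fxp <- extract_features(sim$volumes[part$subject_id], mask = fx$mask)
    estimate_brain_age(
      est, fxp$features,
      data.frame(subject_id = part$subject_id, sex = part$sex,
                 age = part$chronological_age),
      mask_checksum = fxp$mask_checksum
    )
  }
  list(sim = sim, features = fx, estimator = est,
       eval_results = score_role("eval"), mci_results = score_role("mci"))
}
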