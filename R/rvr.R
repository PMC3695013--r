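#' Kernel specification for relevance vector regression
#'
#' Only integer-degree polynomial kernels are supported; age estimation from
#' smoothed gray-matter maps works well with the degree-1 (linear) kernel,
#' and nonlinear kernels have not been found to improve it.
#'
#' @param degree Polynomial degree (integer >= 1; default 1).
#' @param include_bias Append a constant bias column to the design
#'   (default `TRUE`). Ages are far from zero, so the bias matters for a
#'   linear kernel.
#' @return An object of class `kernel_spec`.
#' @export
kernel_spec <- function(degree = 1L, include_bias = TRUE) {
  degree <- as.integer(degree)
  if (is.na(degree) || degree < 1L) abort("`degree` must be an integer >= 1.")
  structure(list(kind = "polynomial", degree = degree,
                 include_bias = isTRUE(include_bias)),
            class = "kernel_spec")
}

#' Polynomial kernel matrix
#'
#' Entry (i, j) is `(<a_i, b_j>)^degree` for row i of `rows_a` and row j of
#' `rows_b`. The bias column of the design is handled by
#' [rvr_design()], not here.
#'
#' @param rows_a,rows_b Numeric matrices with matching feature dimension.
#' @param spec A [kernel_spec()].
#' @return Matrix of dimension `nrow(rows_a)` x `nrow(rows_b)`.
#' @export
kernel_matrix <- function(rows_a, rows_b, spec = kernel_spec()) {
  if (is.null(dim(rows_a))) rows_a <- matrix(rows_a, nrow = 1)
  if (is.null(dim(rows_b))) rows_b <- matrix(rows_b, nrow = 1)
  if (ncol(rows_a) != ncol(rows_b)) {
    abort(sprintf("dimension mismatch: %d vs %d features.",
                  ncol(rows_a), ncol(rows_b)))
  }
  (rows_a %*% t(rows_b))^spec$degree
}

#' Design matrix over a training basis
#'
#' Kernel evaluations of `rows` against the `basis` rows, with a constant
#' bias column appended when the kernel spec asks for one.
#'
#' @inheritParams kernel_matrix
#' @param rows Rows to evaluate.
#' @param basis Training rows serving as basis functions.
#' @return Design matrix with `nrow(basis) + include_bias` columns.
#' @export
rvr_design <- function(rows, basis, spec = kernel_spec()) {
  k <- kernel_matrix(rows, basis, spec)
  if (spec$include_bias) {
    k <- cbind(k, 1)
    attr(k, "bias_col") <- ncol(k)
  }
  k
}

#' Optimizer constants for relevance vector regression
#'
#' These are the free constants of the sparse Bayesian learning procedure;
#' the model's real parameters (weights, their precisions, the noise
#' variance) are estimated automatically from the data.
#'
#' @param max_iterations Cap on re-estimation iterations.
#' @param alpha_prune_threshold A basis function whose weight precision
#'   exceeds this is pruned (its weight is pinned at zero).
#' @param convergence_tol Stop when `max |delta log alpha|` over surviving
#'   basis functions falls below this.
#' @param init_alpha Initial weight precision for every basis function.
#' @param init_noise_variance Initial noise variance; default
#'   `0.1 * var(y)`.
#' @param update_alpha,update_sigma Disable the corresponding hyperparameter
#'   updates (used to check the fixed-precision closed forms; leave `TRUE`
#'   for real fits).
#' @param seed Reserved; the fit itself is deterministic.
#' @return An object of class `rvr_config`.
#' @export
rvr_config <- function(max_iterations = 1000L, alpha_prune_threshold = 1e12,
                       convergence_tol = 1e-3, init_alpha = 1e-6,
                       init_noise_variance = NULL, update_alpha = TRUE,
                       update_sigma = TRUE, seed = NULL) {
  stopifnot(max_iterations >= 1, alpha_prune_threshold > 0,
            convergence_tol > 0, init_alpha > 0)
  structure(list(max_iterations = as.integer(max_iterations),
                 alpha_prune_threshold = alpha_prune_threshold,
                 convergence_tol = convergence_tol,
                 init_alpha = init_alpha,
                 init_noise_variance = init_noise_variance,
                 update_alpha = isTRUE(update_alpha),
                 update_sigma = isTRUE(update_sigma),
                 seed = seed),
            class = "rvr_config")
}

# Posterior covariance/mean for the active basis at fixed (alpha, sigma2).
# Solved through the QR factorization of the square-root augmented system
# [phi/sigma; diag(sqrt(alpha))] so the conditioning is the square root of
# the normal-equation formulation (essential when sigma2 collapses on
# noiseless data). Falls back to a jittered Cholesky of the precision if
# the QR is rank-deficient. Returns Sigma, mu, and log|H| with
# H = phi'phi/sigma2 + diag(alpha) (for the marginal likelihood).
rvr_posterior <- function(phi, y, alpha, sigma2) {
  m <- length(alpha)
  aug <- rbind(phi / sqrt(sigma2), diag(sqrt(alpha), m))
  qrf <- qr(aug)
  if (qrf$rank == m) {
    r <- qr.R(qrf)
    rinv <- backsolve(r, diag(m))
    sigma_post <- tcrossprod(rinv)
    qty <- qr.qty(qrf, c(y / sqrt(sigma2), rep(0, m)))[seq_len(m)]
    mu <- drop(backsolve(r, qty))
    return(list(Sigma = sigma_post, mu = mu,
                logdet_H = 2 * sum(log(abs(diag(r))))))
  }
  h <- crossprod(phi) / sigma2 + diag(alpha, m)
  scale <- mean(diag(h))
  jitter <- 0
  repeat {
    ch <- tryCatch(chol(h + diag(jitter, m)), error = function(e) NULL)
    if (!is.null(ch)) break
    jitter <- if (jitter == 0) 1e-10 * scale else jitter * 100
    if (jitter > 1e-6 * scale) {
      abort("posterior precision not positive definite.")
    }
  }
  if (jitter > 0) {
    inform(sprintf("rvr: added jitter %g to stabilize the posterior Cholesky.",
                   jitter))
  }
  sigma_post <- chol2inv(ch)
  mu <- drop(sigma_post %*% crossprod(phi, y)) / sigma2
  list(Sigma = sigma_post, mu = mu, logdet_H = 2 * sum(log(diag(ch))))
}

# Marginal log-likelihood of the sparse Bayesian linear model, computed via
# the weight-space identity (avoids forming the n x n covariance):
# log p(y) = -1/2 [ n log 2pi + n log sigma2 - sum log alpha + logdet H
#                   + (y'y - mu' H mu * ... ) ] using the standard identity
# y' C^{-1} y = (y'y - sigma2 * mu' H mu) / sigma2 with H the posterior
# precision and mu its mean.
rvr_marginal_loglik <- function(phi, y, alpha, sigma2, post) {
  n <- length(y)
  quad <- (sum(y^2) - sum(y * (phi %*% post$mu))) / sigma2
  -0.5 * (n * log(2 * pi) + n * log(sigma2) - sum(log(alpha)) +
            post$logdet_H + quad)
}

#' Fit relevance vector regression
#'
#' Sparse Bayesian linear-in-the-design regression with automatic relevance
#' determination. The model is `y = Phi w + e`, `e ~ N(0, sigma2)`, with an
#' independent zero-mean Gaussian prior `w_i ~ N(0, 1/alpha_i)` on every
#' weight. Hyperparameters are re-estimated by the classic fixed-point
#' scheme: with posterior `Sigma = (Phi'Phi/sigma2 + diag(alpha))^-1`,
#' `mu = Sigma Phi'y / sigma2`, each precision is updated as
#' `alpha_i <- gamma_i / mu_i^2` with `gamma_i = 1 - alpha_i Sigma_ii`, and
#' the noise variance as `|y - Phi mu|^2 / (n - sum gamma)`. Basis functions
#' whose precision diverges are pruned; the few survivors are the relevance
#' vectors.
#'
#' @param phi Design matrix (n observations x m basis functions), typically
#'   from [rvr_design()].
#' @param y Numeric targets of length n.
#' @param config An [rvr_config()].
#' @return An object of class `rvr_model` with the retained basis columns
#'   (`active`), the surviving training-example indices
#'   (`relevance_indices`, excluding the bias column), posterior weight
#'   means `mu`, precisions `alpha`, noise variance `sigma2`, posterior
#'   covariance `Sigma`, convergence information and the marginal
#'   log-likelihood trace.
#' @export
fit_rvr <- function(phi, y, config = rvr_config()) {
  phi <- as.matrix(phi)
  y <- as.numeric(y)
  n <- length(y)
  if (nrow(phi) != n) abort("`phi` rows must match length of `y`.")
  if (n < 2L) abort("need at least 2 observations.")
  if (any(!is.finite(phi)) || any(!is.finite(y))) {
    abort("non-finite values in design or targets.")
  }
  m <- ncol(phi)
  col_norm <- sqrt(colSums(phi^2))
  zero_cols <- col_norm == 0
  if (any(zero_cols)) {
    warn(sprintf("pruning %d all-zero design column(s).", sum(zero_cols)))
  }
  active <- which(!zero_cols)
  alpha <- rep(config$init_alpha, length(active))
  y_scale <- max(stats::var(y), mean(y^2), 1)
  sigma2 <- config$init_noise_variance %||%
    max(0.1 * stats::var(y), 1e-6 * y_scale)
  sigma2_floor <- 1e-12 * y_scale

  ll_trace <- numeric(0)
  converged <- FALSE
  post <- NULL
  for (iter in seq_len(config$max_iterations)) {
    phi_a <- phi[, active, drop = FALSE]
    post <- rvr_posterior(phi_a, y, alpha, sigma2)
    ll_trace <- c(ll_trace, rvr_marginal_loglik(phi_a, y, alpha, sigma2, post))
    gamma <- pmin(pmax(1 - alpha * diag(post$Sigma), 1e-12), 1)
    if (!config$update_alpha && !config$update_sigma) { converged <- TRUE; break }
    alpha_new <- alpha
    if (config$update_alpha) {
      alpha_new <- gamma / pmax(post$mu^2, .Machine$double.xmin)
    }
    if (config$update_sigma) {
      rss <- sum((y - phi_a %*% post$mu)^2)
      denom <- max(n - sum(gamma), .Machine$double.eps)
      sigma2 <- max(rss / denom, sigma2_floor)
    }
    keep <- alpha_new < config$alpha_prune_threshold
    if (!any(keep)) { # keep the single best-supported basis function
      keep[which.min(alpha_new)] <- TRUE
    }
    delta <- max(abs(log(alpha_new[keep]) - log(alpha[keep])))
    active <- active[keep]
    alpha <- alpha_new[keep]
    if (delta < config$convergence_tol) {
      phi_a <- phi[, active, drop = FALSE]
      post <- rvr_posterior(phi_a, y, alpha, sigma2)
      ll_trace <- c(ll_trace,
                    rvr_marginal_loglik(phi_a, y, alpha, sigma2, post))
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warn(sprintf("rvr did not converge in %d iterations; returning last state.",
                 config$max_iterations))
  }
  bias_col <- attr(phi, "bias_col")
  structure(
    list(active = active,
         relevance_indices = setdiff(active, bias_col),
         bias_col = bias_col, mu = post$mu, alpha = alpha,
         sigma2 = sigma2, Sigma = post$Sigma, n_basis = m,
         iterations = iter, converged = converged,
         marginal_loglik = ll_trace, config = config),
    class = "rvr_model"
  )
}

#' Predict from a fitted relevance vector regression
#'
#' @param model An [fit_rvr()] result.
#' @param phi Design matrix for the test rows over the *same* basis the
#'   model was fitted on (use [rvr_design()] with the training basis rows).
#' @return A list with `mean` (predictive means) and `variance`
#'   (`sigma2 + k' Sigma k` per test row).
#' @export
predict_rvr <- function(model, phi) {
  stopifnot(inherits(model, "rvr_model"))
  phi <- as.matrix(phi)
  if (ncol(phi) != model$n_basis) {
    abort(sprintf("dimension mismatch: design has %d columns, model expects %d.",
                  ncol(phi), model$n_basis))
  }
  phi_a <- phi[, model$active, drop = FALSE]
  mean <- drop(phi_a %*% model$mu)
  variance <- model$sigma2 + rowSums((phi_a %*% model$Sigma) * phi_a)
  list(mean = mean, variance = variance)
}

#' @export
print.rvr_model <- function(x, ...) {
  cat(sprintf(
    "<rvr_model> %d relevance vector(s) (%d/%d basis columns), sigma2 = %.4g, %d iteration(s)%s\n",
    length(x$relevance_indices), length(x$active), x$n_basis, x$sigma2,
    x$iterations, if (x$converged) "" else " [NOT CONVERGED]"))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
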