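#' Fit principal components on the training sample only
#'
#' Centers the training matrix on its column means and computes an
#' orthonormal component basis by singular value decomposition. All
#' components of nonzero variance (up to the data rank) are retained by
#' default. The fitted transformation is frozen: test subjects are projected
#' with [apply_pca()] using the training mean and basis, never refitted.
#'
#' For reproducibility across linear-algebra backends, each component's sign
#' is fixed so that its largest-magnitude loading is positive.
#'
#' @param train Numeric matrix, training subjects in rows, features in
#'   columns (at least 2 rows).
#' @param n_components Optional cap on the number of retained components;
#'   default keeps every component up to the numerical rank.
#' @param scale. If `TRUE`, z-score features before PCA (off by default).
#' @return An object of class `pca_model` with fields `mean_vector`,
#'   `scale_vector` (or `NULL`), `components` (rows = components),
#'   `explained_variance` and `n_components`.
#' @export
fit_pca <- function(train, n_components = NULL, scale. = FALSE) {
  train <- as.matrix(train)
  if (nrow(train) < 2L) abort("PCA needs at least 2 training rows.")
  if (any(!is.finite(train))) abort("training matrix has non-finite entries.")
  mu <- colMeans(train)
  xc <- sweep(train, 2, mu)
  sc <- NULL
  if (isTRUE(scale.)) {
    sc <- apply(train, 2, sd)
    sc[sc == 0] <- 1
    xc <- sweep(xc, 2, sc, "/")
  }
  sv <- svd(xc)
  # numerical rank: discard directions with negligible singular value
  tol <- max(dim(xc)) * .Machine$double.eps * sv$d[1]
  keep <- which(sv$d > max(tol, 0))
  if (!is.null(n_components)) keep <- keep[seq_len(min(n_components, length(keep)))]
  comps <- t(sv$v[, keep, drop = FALSE])
  # sign convention: largest-|loading| entry of each component positive
  for (i in seq_len(nrow(comps))) {
    j <- which.max(abs(comps[i, ]))
    if (comps[i, j] < 0) comps[i, ] <- -comps[i, ]
  }
  structure(
    list(mean_vector = mu, scale_vector = sc, components = comps,
         explained_variance = sv$d[keep]^2 / (nrow(train) - 1),
         n_components = length(keep)),
    class = "pca_model"
  )
}

#' Project rows onto a fitted principal-component basis
#'
#' Applies the frozen training transformation (centering, optional scaling,
#' projection) to new rows. No statistic of the projected rows is ever used
#' to update the model.
#'
#' @param model A [fit_pca()] result.
#' @param rows Numeric matrix (or single vector) with the training feature
#'   dimension.
#' @return Score matrix, one row per input row, `model$n_components` columns.
#' @export
apply_pca <- function(model, rows) {
  stopifnot(inherits(model, "pca_model"))
  if (is.null(dim(rows))) rows <- matrix(rows, nrow = 1)
  rows <- as.matrix(rows)
  if (ncol(rows) != length(model$mean_vector)) {
    abort(sprintf("dimension mismatch: rows have %d features, model expects %d.",
                  ncol(rows), length(model$mean_vector)))
  }
  xc <- sweep(rows, 2, model$mean_vector)
  if (!is.null(model$scale_vector)) xc <- sweep(xc, 2, model$scale_vector, "/")
  scores <- xc %*% t(model$components)
  colnames(scores) <- paste0("PC", seq_len(model$n_components))
  scores
}

#' @export
print.pca_model <- function(x, ...) {
  cat(sprintf("<pca_model> %d components over %d features\n",
              x$n_components, length(x$mean_vector)))
  invisible(x)
}
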