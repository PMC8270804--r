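#' Principal component analysis with eigenvalue retention
#'
#' PCA of the training feature table on the correlation matrix (features
#' are z-scored with training means and SDs), retaining every component
#' whose eigenvalue is strictly greater than the cutoff (default 3).
#' Constant (zero-variance) features are dropped with a warning and
#' recorded in the model. The sign of each loading vector is fixed so that
#' its largest-magnitude entry is positive, making the decomposition
#' deterministic.
#'
#' @param train_features numeric matrix or data.frame, lesions x features.
#' @param eigenvalue_cutoff retention cutoff on the correlation-matrix
#'   eigenvalues (default 3; strictly greater-than).
#' @return object of class `pca_model`: `center`, `scale`, `loadings`
#'   (features x retained), `eigenvalues` (all), `n_retained`,
#'   `dropped_features`, `feature_names`.
#' @export
fit_pca <- function(train_features, eigenvalue_cutoff = 3) {
  x <- as.matrix(train_features)
  if (nrow(x) < 2) stop("PCA needs at least 2 training lesions")
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  sds <- apply(x, 2, stats::sd)
  dropped <- colnames(x)[sds == 0 | !is.finite(sds)]
  if (length(dropped))
    warning("dropping constant feature(s): ", paste(dropped, collapse = ", "))
  keep <- setdiff(colnames(x), dropped)
  x <- x[, keep, drop = FALSE]
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  z <- scale(x, center = ctr, scale = scl)
  r <- stats::cor(x)
  e <- eigen(r, symmetric = TRUE)
  # deterministic sign: largest-|loading| entry positive
  for (j in seq_len(ncol(e$vectors))) {
    k <- which.max(abs(e$vectors[, j]))
    if (e$vectors[k, j] < 0) e$vectors[, j] <- -e$vectors[, j]
  }
  n_ret <- sum(e$values > eigenvalue_cutoff)
  if (n_ret == 0)
    stop("no component exceeds the eigenvalue cutoff of ", eigenvalue_cutoff)
  loadings <- e$vectors[, seq_len(n_ret), drop = FALSE]
  rownames(loadings) <- keep
  colnames(loadings) <- paste0("PC", seq_len(n_ret))
  structure(list(center = ctr, scale = scl, loadings = loadings,
                 eigenvalues = e$values, n_retained = n_ret,
                 eigenvalue_cutoff = eigenvalue_cutoff,
                 dropped_features = dropped, feature_names = keep),
            class = "pca_model")
}

#' Project lesions onto retained components
#'
#' Applies the training standardization (no leakage: held-out lesions use
#' training means and SDs) and the retained loadings.
#'
#' @param model a `pca_model`.
#' @param features matrix/data.frame (lesions x features) or a single
#'   named feature vector; must contain the training feature schema.
#' @return matrix of component scores, lesions x retained components.
#' @export
pca_project <- function(model, features) {
  if (is.null(dim(features))) features <- t(as.matrix(features))
  x <- as.matrix(features)
  if (!all(model$feature_names %in% colnames(x)))
    stop("feature schema mismatch: missing ",
         paste(setdiff(model$feature_names, colnames(x)), collapse = ", "))
  x <- x[, model$feature_names, drop = FALSE]
  z <- sweep(sweep(x, 2, model$center), 2, model$scale, "/")
  z %*% model$loadings
}

#' @export
print.pca_model <- function(x, ...) {
  cat(sprintf(
    "PCA model: %d features, %d component(s) retained (eigenvalue > %g)\n",
    length(x$feature_names), x$n_retained, x$eigenvalue_cutoff))
  cat("top eigenvalues:", paste(signif(utils::head(x$eigenvalues, 6), 4),
                                collapse = ", "), "\n")
  invisible(x)
}

#' Serialize a PCA model to JSON
#' @param model a `pca_model`.
#' @param path file path.
#' @export
write_pca_json <- function(model, path) {
  jsonlite::write_json(
    list(center = as.list(model$center), scale = as.list(model$scale),
         loadings = model$loadings, eigenvalues = model$eigenvalues,
         n_retained = model$n_retained,
         eigenvalue_cutoff = model$eigenvalue_cutoff,
         dropped_features = model$dropped_features),
    path, digits = NA, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
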