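# PCA on training features; projection of train and test into the principal
# subspace.  Fitting uses the training rows only (leakage-safe per fold).

#' Fit a PCA model on training features
#'
#' Centers by the training mean and decomposes the training covariance
#' (unbiased, n-1 denominator) via the singular value decomposition of the
#' centered data ([stats::prcomp]), which is numerically equivalent to an
#' eigendecomposition of the explicitly formed covariance matrix. Retains the
#' smallest number of leading components whose cumulative eigenvalue fraction
#' reaches `retain`, or exactly `k` components when `k` is given. Component
#' signs are canonicalized by making each component's largest-magnitude
#' coordinate positive, so fits are fully deterministic.
#'
#' @param train A [psd_feature_matrix()] or plain numeric matrix (rows =
#'   samples); at least 2 rows.
#' @param retain Cumulative explained-variance fraction to retain (default
#'   0.95); ignored when `k` is given.
#' @param k Exact number of components (optional); must not exceed the
#'   numerical rank of the training covariance.
#' @return A `pca_model`: `mean_vector`, `components` (p x k orthonormal
#'   columns), `eigenvalues` (all, descending), `n_components_retained`,
#'   `explained_variance_fraction`.
#' @export
fit_pca <- function(train, retain = 0.95, k = NULL) {
  x <- if (inherits(train, "psd_feature_matrix")) train$values else as.matrix(train)
  if (nrow(x) < 2) stop("PCA requires more than one row")
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  eig <- pc$sdev^2
  rank <- sum(eig > max(eig) * 1e-12)
  if (!is.null(k)) {
    if (k > rank) {
      stop("requested ", k, " components but training covariance has rank ", rank)
    }
    n_comp <- as.integer(k)
  } else {
    if (retain <= 0 || retain > 1) stop("retain must be in (0, 1]")
    frac <- cumsum(eig) / sum(eig)
    n_comp <- min(which(frac >= retain - 1e-12))
    n_comp <- min(n_comp, rank)
  }
  comp <- unname(pc$rotation[, seq_len(n_comp), drop = FALSE])
  # sign canonicalization: largest-magnitude coordinate positive
  for (j in seq_len(ncol(comp))) {
    i <- which.max(abs(comp[, j]))
    if (comp[i, j] < 0) comp[, j] <- -comp[, j]
  }
  structure(list(mean_vector = unname(pc$center), components = comp,
                 eigenvalues = eig, n_components_retained = n_comp,
                 explained_variance_fraction = sum(eig[seq_len(n_comp)]) / sum(eig)),
            class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  cat("<pca_model> ", x$n_components_retained, " components, ",
      sprintf("%.1f%%", 100 * x$explained_variance_fraction),
      " variance explained\n", sep = "")
  invisible(x)
}

#' Project features into the principal subspace
#'
#' Subtracts the training mean and projects onto the retained components.
#' Labels (when present on a [psd_feature_matrix()] input) are carried
#' through unchanged as the `labels` attribute.
#'
#' @param object A `pca_model`.
#' @param newdata A [psd_feature_matrix()] or numeric matrix with the same
#'   number of columns the model was fit on.
#' @param ... Unused.
#' @return Numeric score matrix (rows x retained components), with a
#'   `labels` attribute when the input was labelled.
#' @export
predict.pca_model <- function(object, newdata, ...) {
  labels <- NULL
  x <- if (inherits(newdata, "psd_feature_matrix")) {
    labels <- newdata$labels
    newdata$values
  } else as.matrix(newdata)
  if (ncol(x) != length(object$mean_vector)) {
    stop("dimension mismatch: model fit on ", length(object$mean_vector),
         " features, data has ", ncol(x))
  }
  scores <- sweep(x, 2L, object$mean_vector) %*% object$components
  if (!is.null(labels)) attr(scores, "labels") <- labels
  scores
}
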