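#' Preprocessing configuration
#'
#' Describes the preprocessing chain applied to contact distances before
#' similarity computation, in the fixed order smoothing -> normalization ->
#' PCA.
#'
#' @param smooth_sigma Gaussian filter standard deviation in frames
#'   (nonnegative integer; 0 = off).
#' @param normalization One of `"none"`, `"time_resolved"` (divide each
#'   element by its per-time-step ensemble mean) or `"global"` (pooled
#'   per-contact standardization to zero mean, unit variance).
#' @param pca_components Optional integer vector of principal components to
#'   keep (e.g. `1:4`); `NULL` disables PCA.
#' @param smooth_truncate Kernel truncation radius in units of
#'   `smooth_sigma` (default 1: window of plus/minus sigma frames).
#' @return An object of class `preprocess_config`.
#' @export
preprocess_config <- function(smooth_sigma = 0,
                              normalization = c("none", "time_resolved", "global"),
                              pca_components = NULL,
                              smooth_truncate = 1) {
  normalization <- match.arg(normalization)
  if (smooth_sigma < 0) stop("smooth_sigma must be >= 0")
  if (!is.null(pca_components)) {
    pca_components <- as.integer(pca_components)
    if (any(pca_components < 1)) stop("pca_components must be >= 1")
  }
  structure(list(smooth_sigma = as.integer(smooth_sigma),
                 normalization = normalization,
                 pca_components = pca_components,
                 smooth_truncate = smooth_truncate),
            class = "preprocess_config")
}

#' @export
print.preprocess_config <- function(x, ...) {
  cat("preprocess_config:", preprocess_fingerprint(x), "\n")
  invisible(x)
}

# short provenance string, e.g. "sigma=5,nt,PC1-4"
preprocess_fingerprint <- function(config) {
  parts <- character(0)
  if (config$smooth_sigma > 0)
    parts <- c(parts, paste0("sigma=", config$smooth_sigma))
  if (config$normalization == "time_resolved") parts <- c(parts, "nt")
  if (config$normalization == "global") parts <- c(parts, "n")
  if (!is.null(config$pca_components))
    parts <- c(parts, paste0("PC", min(config$pca_components), "-",
                             max(config$pca_components)))
  if (length(parts) == 0) "raw" else paste(parts, collapse = ",")
}

#' Temporal Gaussian smoothing of a contact trajectory
#'
#' Convolves each contact-distance column with a normalized Gaussian kernel
#' of standard deviation `sigma` frames, truncated at plus/minus
#' `truncate * sigma` frames. At the series edges the truncated kernel is
#' renormalized over the available frames (no padding), so constant series
#' are preserved exactly. `sigma = 0` returns the input unchanged.
#'
#' @param traj A [contact_trajectory].
#' @param sigma Kernel standard deviation in frames (nonnegative integer).
#' @param truncate Truncation radius in units of sigma (default 1).
#' @return A smoothed [contact_trajectory].
#' @export
gaussian_smooth <- function(traj, sigma, truncate = 1) {
  stopifnot(inherits(traj, "contact_trajectory"))
  if (sigma < 0) stop("sigma must be >= 0")
  if (sigma == 0) return(traj)
  half <- max(1L, as.integer(ceiling(truncate * sigma)))
  nu <- seq(-half, half)
  w <- exp(-nu^2 / (2 * sigma^2))
  k <- nrow(traj$values)
  sm <- matrix(0, k, ncol(traj$values))
  # edge-renormalized convolution; K is small enough that the explicit loop
  # over offsets (2*half+1 terms) dominates nothing downstream
  wsum <- numeric(k)
  for (j in seq_along(nu)) {
    src <- seq_len(k) + nu[j]
    ok <- src >= 1 & src <= k
    sm[ok, ] <- sm[ok, ] + w[j] * traj$values[src[ok], , drop = FALSE]
    wsum[ok] <- wsum[ok] + w[j]
  }
  sm <- sm / wsum
  new_contact_trajectory(sm, dt = traj$dt, traj_id = traj$traj_id,
                         contact_labels = traj$contact_labels)
}

#' Time-resolved normalization of an ensemble
#'
#' Divides each entry by the mean of the same matrix element across all
#' trajectories, so that after the transform the ensemble mean of every
#' (time step, contact) element is exactly 1. Counteracts the growth of
#' absolute distances during free diffusion in the unbound state.
#' Requires all trajectories to share the same number of time steps.
#'
#' @param ensemble A [trajectory_ensemble] with aligned (equal-K)
#'   trajectories and strictly positive element means.
#' @param tol Positivity guard for the element means (default 1e-12 nm).
#' @return The normalized [trajectory_ensemble].
#' @export
time_normalize <- function(ensemble, tol = 1e-12) {
  stopifnot(inherits(ensemble, "trajectory_ensemble"))
  if (!equal_lengths(ensemble))
    stop("time-resolved normalization requires aligned trajectories of equal length")
  mu <- Reduce(`+`, lapply(ensemble$trajectories, `[[`, "values")) /
    length(ensemble)
  if (any(mu <= tol)) {
    idx <- which(mu <= tol, arr.ind = TRUE)[1, ]
    stop(sprintf("element mean not positive at (t = %d, m = %d)",
                 idx[1], idx[2]))
  }
  map_ensemble(ensemble, function(v) v / mu)
}

#' Global standardization of an ensemble
#'
#' Standardizes each contact column to zero mean and unit variance, pooling
#' over all trajectories and time steps (population variance, divisor
#' `N * K`), bringing all input features to a common scale.
#'
#' @param ensemble A [trajectory_ensemble].
#' @param tol Guard against zero-variance columns.
#' @return The standardized [trajectory_ensemble].
#' @export
global_standardize <- function(ensemble, tol = 1e-12) {
  stopifnot(inherits(ensemble, "trajectory_ensemble"))
  pooled <- pool_values(ensemble)
  mu <- colMeans(pooled)
  sig2 <- colMeans(sweep(pooled, 2, mu)^2)   # population variance
  if (any(sig2 <= tol)) {
    m <- which(sig2 <= tol)[1]
    stop(sprintf("contact column %d ('%s') has zero variance",
                 m, ensemble$contact_labels[m]))
  }
  sig <- sqrt(sig2)
  map_ensemble(ensemble, function(v)
    sweep(sweep(v, 2, mu), 2, sig, "/"))
}

#' Contact principal component analysis
#'
#' Diagonalizes the covariance matrix of the contact distances pooled over
#' all trajectories and time steps (divisor `N * K`). The eigenvector
#' composition reveals the relative contribution of each contact; the
#' projection is unitary, so keeping all components preserves pairwise
#' Euclidean frame distances.
#'
#' @param ensemble A [trajectory_ensemble].
#' @return An object of class `pca_model` with elements `eigenvectors`
#'   (`M x M`, columns orthonormal), `eigenvalues` (descending,
#'   nonnegative), `means` (per-contact mean) and `contact_labels`.
#' @export
fit_pca <- function(ensemble) {
  stopifnot(inherits(ensemble, "trajectory_ensemble"))
  pooled <- pool_values(ensemble)
  mu <- colMeans(pooled)
  centered <- sweep(pooled, 2, mu)
  covm <- crossprod(centered) / nrow(centered)   # divisor N*K
  eig <- eigen(covm, symmetric = TRUE)
  lambda <- pmax(eig$values, 0)
  structure(list(eigenvectors = eig$vectors, eigenvalues = lambda,
                 means = mu, contact_labels = ensemble$contact_labels),
            class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  tot <- sum(x$eigenvalues)
  cat(sprintf("pca_model: %d components, leading eigenvalues:\n",
              length(x$eigenvalues)))
  k <- min(4, length(x$eigenvalues))
  for (i in seq_len(k))
    cat(sprintf("  PC%d: lambda = %.4g (%.1f%%)\n", i, x$eigenvalues[i],
                100 * x$eigenvalues[i] / tot))
  invisible(x)
}

#' Project an ensemble onto principal components
#'
#' @param ensemble A [trajectory_ensemble] on the same contact set the
#'   model was fitted on.
#' @param model A `pca_model` from [fit_pca()].
#' @param components Integer vector of components to keep (default all).
#' @return A [trajectory_ensemble] whose columns are the projections
#'   `PC_k(t)` (data centered by the fitted means).
#' @export
project_pca <- function(ensemble, model,
                        components = seq_along(model$eigenvalues)) {
  stopifnot(inherits(ensemble, "trajectory_ensemble"),
            inherits(model, "pca_model"))
  m <- length(model$eigenvalues)
  components <- as.integer(components)
  if (any(components < 1) || any(components > m))
    stop("components out of range [1, ", m, "]")
  ev <- model$eigenvectors[, components, drop = FALSE]
  map_ensemble(ensemble, function(v) {
    proj <- sweep(v, 2, model$means) %*% ev
    colnames(proj) <- paste0("PC", components)
    proj
  })
}

#' Export a PCA model as a delimited table
#'
#' One row per contact with the eigenvector components, plus a header
#' comment with the eigenvalues, for interpreting contact contributions.
#'
#' @param model A `pca_model`.
#' @param file Output TSV path.
#' @return `file`, invisibly.
#' @export
write_pca_model <- function(model, file) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(paste0("# eigenvalues: ",
                    paste(sprintf("%.17g", model$eigenvalues),
                          collapse = "\t")), con)
  df <- data.frame(contact = model$contact_labels, mean = model$means,
                   model$eigenvectors, check.names = FALSE)
  names(df)[-(1:2)] <- paste0("e", seq_along(model$eigenvalues))
  utils::write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Apply a preprocessing chain to an ensemble
#'
#' Applies, in order: Gaussian smoothing, normalization, PCA projection,
#' as described by a [preprocess_config]. The order is fixed; each step is
#' skipped when disabled in the config.
#'
#' @param ensemble A [trajectory_ensemble].
#' @param config A [preprocess_config].
#' @return The preprocessed [trajectory_ensemble]; the applied chain is
#'   recorded in attribute `"preprocessing"`.
#' @export
apply_preprocess <- function(ensemble, config = preprocess_config()) {
  stopifnot(inherits(ensemble, "trajectory_ensemble"),
            inherits(config, "preprocess_config"))
  out <- ensemble
  if (config$smooth_sigma > 0) {
    out <- trajectory_ensemble(
      lapply(out$trajectories, gaussian_smooth, sigma = config$smooth_sigma,
             truncate = config$smooth_truncate),
      labels = out$labels)
  }
  out <- switch(config$normalization,
                none = out,
                time_resolved = time_normalize(out),
                global = global_standardize(out))
  if (!is.null(config$pca_components)) {
    model <- fit_pca(out)
    out <- project_pca(out, model, config$pca_components)
    attr(out, "pca_model") <- model
  }
  attr(out, "preprocessing") <- preprocess_fingerprint(config)
  out
}
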