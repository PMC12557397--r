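#' @useDynLib pathsep, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

traj_values <- function(x) {
  if (inherits(x, "contact_trajectory")) x$values else as.matrix(x)
}

#' Mean Euclidean distance between two trajectories
#'
#' The per-time-step Euclidean distance across the M contact features,
#' averaged over all time steps. Requires equal-length, time-aligned
#' trajectories (satisfied for constraint pulling started from a common
#' initial distance).
#'
#' @param a,b [contact_trajectory] objects (or plain `K x M` matrices)
#'   with equal K and M.
#' @return Nonnegative scalar distance (nm per frame-vector).
#' @export
mean_euclidean <- function(a, b) {
  va <- traj_values(a); vb <- traj_values(b)
  if (ncol(va) != ncol(vb))
    stop("trajectories must share the same number of contacts")
  if (nrow(va) != nrow(vb))
    stop("Euclidean distance requires equal-length, aligned trajectories")
  mean(sqrt(rowSums((va - vb)^2)))
}

#' Dependent dynamic time warping distance
#'
#' Multivariate (dependent) DTW: a dynamic program over the `K x K'` grid
#' accumulates squared per-frame Euclidean costs along warping paths with
#' steps down/right/diagonal, boundary `(1,1)` to `(K,K')` and monotone
#' indices. Allows nonlinear time alignment of unequal-length trajectories.
#' By default the square root of the minimal cumulative squared cost is
#' returned so the value stays on the nm scale; `squared = TRUE` returns
#' the raw cumulative cost. No window/band constraint is applied.
#'
#' @param a,b [contact_trajectory] objects (or matrices) with equal M;
#'   lengths may differ.
#' @param squared Return the raw minimal cumulative squared cost.
#' @return Nonnegative scalar; 0 iff one series is a monotone duplication
#'   of the other.
#' @export
dtw_dependent <- function(a, b, squared = FALSE) {
  va <- traj_values(a); vb <- traj_values(b)
  if (ncol(va) != ncol(vb))
    stop("trajectories must share the same number of contacts")
  cost <- dtw_dependent_cost(va, vb)
  if (squared) cost else sqrt(cost)
}

#' Procrustes disparity between two trajectories
#'
#' Compares trajectory matrices as point clouds in contact space: both are
#' column-centered and scaled to unit Frobenius norm, then optimally
#' superimposed by an orthogonal map (reflections allowed) and scaling
#' obtained from the singular value decomposition. The returned disparity
#' is the residual sum of squares after superposition, capturing
#' differences in shape rather than position, size or orientation.
#' Following the field's practice, trajectories are downsampled by
#' `stride` (default every 5th time step) since the computation scales
#' steeply with K and the striding does not materially change the
#' similarities.
#'
#' @param a,b [contact_trajectory] objects (or matrices) with equal K and
#'   M after striding.
#' @param stride Positive integer downsampling step (default 5).
#' @return Disparity in `[0, 1]` for the standardized matrices.
#' @export
procrustes_distance <- function(a, b, stride = 5) {
  va <- traj_values(a); vb <- traj_values(b)
  if (stride < 1) stop("stride must be a positive integer")
  va <- va[seq(1, nrow(va), by = stride), , drop = FALSE]
  vb <- vb[seq(1, nrow(vb), by = stride), , drop = FALSE]
  if (ncol(va) != ncol(vb))
    stop("trajectories must share the same number of contacts")
  if (nrow(va) != nrow(vb))
    stop("Procrustes analysis requires equal-length trajectories after striding")
  if (nrow(va) < 2) stop("need at least 2 time steps after striding")
  std <- function(v) {
    v <- sweep(v, 2, colMeans(v))
    nrm <- sqrt(sum(v^2))
    if (nrm <= 0) stop("degenerate (constant) trajectory")
    v / nrm
  }
  va <- std(va); vb <- std(vb)
  sv <- svd(crossprod(vb, va))
  rot <- sv$u %*% t(sv$v)
  scale <- sum(sv$d)
  sum((va - scale * vb %*% rot)^2)
}

#' Summed one-dimensional Wasserstein distance
#'
#' Treats each contact-distance column as an empirical distribution over
#' the sampled values (uniform weight 1/K per time step, discarding time
#' order) and computes the order-1 Wasserstein (earth mover's) distance
#' between the two distributions; the per-contact distances are summed
#' over the M contacts. A true metric, invariant to any permutation of
#' time steps, and applicable to unequal-length trajectories.
#'
#' @param a,b [contact_trajectory] objects (or matrices) with equal M.
#' @return Nonnegative scalar distance (nm).
#' @export
wasserstein_distance <- function(a, b) {
  va <- traj_values(a); vb <- traj_values(b)
  if (ncol(va) != ncol(vb))
    stop("trajectories must share the same number of contacts")
  if (nrow(va) < 1 || nrow(vb) < 1) stop("empty columns")
  total <- 0
  for (m in seq_len(ncol(va)))
    total <- total + wasserstein_1d(va[, m], vb[, m])
  total
}

# order-1 Wasserstein distance between two uniform-weight samples:
# integral over the pooled support of |F_a - F_b|
wasserstein_1d <- function(x, y) {
  sx <- sort(x); sy <- sort(y)
  all <- sort(c(sx, sy))
  grid <- all[-length(all)]
  fa <- findInterval(grid, sx) / length(sx)
  fb <- findInterval(grid, sy) / length(sy)
  sum(abs(fa - fb) * diff(all))
}

#' Pairwise distance matrix over an ensemble
#'
#' Computes all `N (N - 1) / 2` pairwise trajectory distances under one
#' measure. Pair evaluations are pure, so the result is independent of
#' evaluation order.
#'
#' @param ensemble A [trajectory_ensemble] (typically preprocessed via
#'   [apply_preprocess()]).
#' @param measure One of `"euclidean"`, `"dtw"`, `"procrustes"`,
#'   `"wasserstein"`.
#' @param stride Procrustes downsampling stride (ignored otherwise).
#' @return Symmetric `N x N` matrix of class `trajdist` with zero
#'   diagonal; trajectory ids as dimnames, the measure and preprocessing
#'   fingerprint as attributes.
#' @export
distance_matrix <- function(ensemble,
                            measure = c("euclidean", "dtw", "procrustes",
                                        "wasserstein"),
                            stride = 5) {
  stopifnot(inherits(ensemble, "trajectory_ensemble"))
  measure <- match.arg(measure)
  n <- length(ensemble)
  fun <- switch(measure,
                euclidean = mean_euclidean,
                dtw = dtw_dependent,
                procrustes = function(a, b) procrustes_distance(a, b, stride),
                wasserstein = wasserstein_distance)
  d <- matrix(0, n, n)
  ids <- vapply(ensemble$trajectories, `[[`, character(1), "traj_id")
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      val <- tryCatch(fun(ensemble$trajectories[[i]],
                          ensemble$trajectories[[j]]),
                      error = function(e)
                        stop(sprintf("pair (%s, %s): %s", ids[i], ids[j],
                                     conditionMessage(e)), call. = FALSE))
      d[i, j] <- d[j, i] <- val
    }
  }
  dimnames(d) <- list(ids, ids)
  structure(d, measure = measure,
            preprocessing = attr(ensemble, "preprocessing") %||% "raw",
            class = c("trajdist", "matrix", "array"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Convert a distance matrix to a similarity matrix
#'
#' `s_ij = 1 - d_ij / d_max`, mapping distances affinely onto `[0, 1]`:
#' the diagonal becomes 1 and the maximally distant pair maps to 0.
#'
#' @param d A `trajdist` matrix from [distance_matrix()] (or any
#'   symmetric nonnegative matrix with zero diagonal).
#' @return An `N x N` matrix of class `trajsim` with unit diagonal,
#'   carrying the measure/preprocessing provenance.
#' @export
to_similarity <- function(d) {
  dmax <- max(d)
  if (dmax <= 0) stop("no contrast between trajectories (all distances zero)")
  s <- 1 - d / dmax
  structure(s, measure = attr(d, "measure"),
            preprocessing = attr(d, "preprocessing"),
            class = c("trajsim", "matrix", "array"))
}

#' @export
print.trajdist <- function(x, ...) {
  cat(sprintf("trajdist: %d x %d, measure = %s, preprocessing = %s\n",
              nrow(x), ncol(x), attr(x, "measure") %||% "?",
              attr(x, "preprocessing") %||% "?"))
  cat(sprintf("  off-diagonal range [%.4g, %.4g]\n",
              min(x[upper.tri(x)]), max(x[upper.tri(x)])))
  invisible(x)
}

#' @export
print.trajsim <- function(x, ...) {
  cat(sprintf("trajsim: %d x %d, measure = %s, preprocessing = %s\n",
              nrow(x), ncol(x), attr(x, "measure") %||% "?",
              attr(x, "preprocessing") %||% "?"))
  cat(sprintf("  off-diagonal range [%.4g, %.4g]\n",
              min(x[upper.tri(x)]), max(x[upper.tri(x)])))
  invisible(x)
}
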