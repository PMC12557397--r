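#' Boltzmann constant in kJ/(mol K)
#' @export
kB <- 0.008314462618

#' Work ensemble on a common pulling-coordinate grid
#'
#' Per-trajectory work curves `W(x)` (kJ/mol) from constant-velocity
#' constraint pulling, sampled on one strictly increasing pulling
#' coordinate grid (nm) shared by all members, with the simulation
#' temperature. Work is zero at the grid origin.
#'
#' @param x_grid Strictly increasing pulling coordinate values in nm.
#' @param works Numeric matrix, `length(x_grid)` rows x N trajectory
#'   columns, in kJ/mol, with `works[1, ] == 0`.
#' @param temperature Simulation temperature in K (required; it is not
#'   assumed).
#' @param traj_ids Optional trajectory identifiers (default column names
#'   or `"t1" ...`).
#' @return An object of class `work_ensemble`.
#' @export
work_ensemble <- function(x_grid, works, temperature, traj_ids = NULL) {
  works <- as.matrix(works)
  if (any(diff(x_grid) <= 0)) stop("x_grid must be strictly increasing")
  if (nrow(works) != length(x_grid))
    stop("works must have one row per grid point")
  if (any(!is.finite(works))) stop("works must be finite")
  if (max(abs(works[1, ])) > 1e-9)
    stop("work must be zero at the first grid point")
  if (missing(temperature) || is.null(temperature) || temperature <= 0)
    stop("a positive temperature (K) is required")
  if (is.null(traj_ids)) traj_ids <- colnames(works)
  if (is.null(traj_ids)) traj_ids <- paste0("t", seq_len(ncol(works)))
  colnames(works) <- traj_ids
  structure(list(x_grid = as.numeric(x_grid), works = works,
                 temperature = as.numeric(temperature),
                 traj_ids = as.character(traj_ids)),
            class = "work_ensemble")
}

#' @export
print.work_ensemble <- function(x, ...) {
  cat(sprintf("work_ensemble: %d trajectories on %d grid points, x in [%.3g, %.3g] nm, T = %g K\n",
              ncol(x$works), length(x$x_grid), min(x$x_grid), max(x$x_grid),
              x$temperature))
  invisible(x)
}

#' Integrate constraint forces to work curves
#'
#' Cumulative trapezoidal integration of the constraint force
#' `f_c(x)` (kJ/mol/nm) along the pulling coordinate:
#' `W(x) = int_{x_0}^{x} f_c(x') dx'`, so `W(x_0) = 0`.
#'
#' @param forces Numeric matrix of forces, one row per grid point, one
#'   column per trajectory.
#' @param x_grid Strictly increasing pulling coordinate (nm).
#' @param temperature Simulation temperature in K.
#' @param traj_ids Optional trajectory ids.
#' @return A [work_ensemble].
#' @export
integrate_work <- function(forces, x_grid, temperature, traj_ids = NULL) {
  forces <- as.matrix(forces)
  if (any(diff(x_grid) <= 0)) stop("x_grid must be strictly increasing")
  if (any(!is.finite(forces))) stop("forces must be finite")
  w <- apply(forces, 2, function(f) pracma::cumtrapz(x_grid, f))
  work_ensemble(x_grid, w, temperature = temperature, traj_ids = traj_ids)
}

#' Free-energy profile via the second-order cumulant expansion
#'
#' Estimates `dG(x) = <W(x)> - <dW(x)^2> / (2 kB T)` pointwise from an
#' ensemble of nonequilibrium work curves (dissipation-corrected targeted
#' MD). The correction term is the dissipative work
#' `W_diss(x) = var(W(x)) / (2 kB T)`; the expansion is exact when the
#' work distribution is Gaussian. By default the unbiased (`N - 1`)
#' variance estimator is used.
#'
#' @param works A [work_ensemble] with at least 2 members.
#' @param biased_variance Use the `N` divisor instead of `N - 1`.
#' @return An object of class `free_energy_profile`: list with `x_grid`,
#'   `deltaG`, `mean_work`, `dissipative_work` (all kJ/mol), `n_used`
#'   and `temperature`.
#' @export
free_energy <- function(works, biased_variance = FALSE) {
  stopifnot(inherits(works, "work_ensemble"))
  n <- ncol(works$works)
  if (n < 2) stop("free energy estimation needs at least N = 2 work curves")
  mw <- rowMeans(works$works)
  v <- apply(works$works, 1, stats::var)
  if (biased_variance) v <- v * (n - 1) / n
  wdiss <- v / (2 * kB * works$temperature)
  structure(list(x_grid = works$x_grid, deltaG = mw - wdiss, mean_work = mw,
                 dissipative_work = wdiss, n_used = n,
                 temperature = works$temperature),
            class = "free_energy_profile")
}

#' @export
print.free_energy_profile <- function(x, ...) {
  cat(sprintf("free_energy_profile: %d grid points, N = %d trajectories\n",
              length(x$x_grid), x$n_used))
  cat(sprintf("  dG range [%.3g, %.3g] kJ/mol, max W_diss = %.3g kJ/mol\n",
              min(x$deltaG), max(x$deltaG), max(x$dissipative_work)))
  invisible(x)
}

#' Per-pathway free-energy profiles
#'
#' Applies [free_energy()] within each cluster of a pathway partition.
#' Trajectories grouped under `"?"` are always skipped; clusters smaller
#' than `min_cluster_size` (default 100, the recommended minimum for a
#' converged cumulant estimate) are skipped with a message.
#'
#' @param works A [work_ensemble] aligned with the partition (same
#'   trajectory order).
#' @param partition A `pathway_partition` (or plain label vector).
#' @param min_cluster_size Minimum cluster size entering the estimate.
#' @return Named list of `free_energy_profile`s, one per qualifying
#'   cluster; empty (with a warning) if no cluster qualifies.
#' @export
pathwise_free_energy <- function(works, partition, min_cluster_size = 100) {
  stopifnot(inherits(works, "work_ensemble"))
  a <- assignment_vector(partition)
  if (length(a) != ncol(works$works))
    stop("partition does not match the work ensemble")
  out <- list()
  for (cl in unique(a)) {
    if (cl == "?") next
    idx <- which(a == cl)
    if (length(idx) < min_cluster_size) {
      message(sprintf("cluster %s: size %d < %d, skipped", cl, length(idx),
                      min_cluster_size))
      next
    }
    sub <- work_ensemble(works$x_grid,
                         works$works[, idx, drop = FALSE],
                         temperature = works$temperature,
                         traj_ids = works$traj_ids[idx])
    out[[cl]] <- free_energy(sub)
  }
  if (length(out) == 0)
    warning("no cluster meets min_cluster_size = ", min_cluster_size)
  out
}

#' Gaussian-work diagnostics
#'
#' The cumulant estimate is exact only for normally distributed work.
#' This returns, at each probe position, quantile-quantile data (sample
#' quantiles of the work against standard normal quantiles) and the
#' Shapiro-Wilk statistic with its p-value. Diagnostics only; nothing is
#' rejected automatically.
#'
#' @param works A [work_ensemble] with at least 8 members.
#' @param x_probe Pulling-coordinate positions to probe (nearest grid
#'   points are used; default: final grid point).
#' @return List of per-probe records with elements `x`, `qq`
#'   (`data.frame` of `theoretical` and `sample` quantiles, sample
#'   centered and scaled), `shapiro_W`, `shapiro_p`.
#' @export
work_normality_diagnostics <- function(works, x_probe = NULL) {
  stopifnot(inherits(works, "work_ensemble"))
  n <- ncol(works$works)
  if (n < 8) stop("normality diagnostics need at least N = 8 work curves")
  if (is.null(x_probe)) x_probe <- works$x_grid[length(works$x_grid)]
  lapply(x_probe, function(xp) {
    i <- which.min(abs(works$x_grid - xp))
    w <- works$works[i, ]
    z <- (sort(w) - mean(w)) / stats::sd(w)
    theo <- stats::qnorm(stats::ppoints(n))
    sw <- stats::shapiro.test(w)
    list(x = works$x_grid[i],
         qq = data.frame(theoretical = theo, sample = z),
         shapiro_W = unname(sw$statistic), shapiro_p = sw$p.value)
  })
}

#' Write a free-energy profile as a delimited table
#'
#' Columns `x`, `deltaG`, `mean_work`, `dissipative_work`, `n_used`.
#'
#' @param profile A `free_energy_profile`.
#' @param file Output TSV path.
#' @return `file`, invisibly.
#' @export
write_free_energy <- function(profile, file) {
  df <- data.frame(x = profile$x_grid, deltaG = profile$deltaG,
                   mean_work = profile$mean_work,
                   dissipative_work = profile$dissipative_work,
                   n_used = profile$n_used)
  utils::write.table(df, file, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(file)
}
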