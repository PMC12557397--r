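#' Synthetic pulling scenario
#'
#' Describes a ground-truth-labeled synthetic unbinding experiment: a
#' point ligand is pulled from the binding site (origin) along one of
#' several Cartesian directions, either with a strict distance constraint
#' (targeted MD: displacement along the pulling direction exactly linear
#' in time) or a harmonic restraint (steered MD: Ornstein-Uhlenbeck
#' fluctuations around `x0 + v t` with stiffness `spring_k`). Contact
#' distances are Euclidean distances to fixed pseudo-residue anchor
#' points plus Gaussian measurement noise.
#'
#' @param directions List of 3-vectors (normalized internally); their
#'   original tuples become the ground-truth labels, e.g. `"(1,1,0)"`.
#' @param n_per_direction Trajectories per direction.
#' @param mode `"constraint"` or `"restraint"`.
#' @param v Pulling velocity in nm/ps.
#' @param dt Frame spacing in ps.
#' @param K Number of frames.
#' @param x0 Initial offset along the pulling direction in nm.
#' @param spring_k Restraint stiffness in kJ/mol/nm^2 (restraint mode).
#' @param ou_tau Relaxation time of the restraint fluctuations in ps.
#' @param lateral_sigma Scale of the lateral random walk in nm (standard
#'   deviation of the accumulated perpendicular excursion at the final
#'   frame).
#' @param noise_sigma Gaussian noise on each contact distance in nm.
#' @param start_sigma Spread of the random start offset in nm.
#' @param temperature Temperature in K (sets the restraint fluctuation
#'   amplitude `kB T / spring_k`).
#' @param n_anchors Number of pseudo-residue anchors.
#' @param anchor_radii Inner/outer radius (nm) of the spherical shell the
#'   anchors are drawn from, centered on the binding site.
#' @param anchors Optional explicit `n x 3` matrix of anchor coordinates
#'   (overrides the generated layout).
#' @param seed Integer seed; the anchor layout uses a fixed sub-seed so
#'   it is shared across scenarios with the same seed.
#' @return An object of class `pathway_scenario`.
#' @export
pathway_scenario <- function(directions = list(c(1, 1, 0), c(1, -1, 0)),
                             n_per_direction = 40,
                             mode = c("restraint", "constraint"),
                             v = 0.01, dt = 1, K = 200, x0 = 0.5,
                             spring_k = 1000, ou_tau = 5 * dt,
                             lateral_sigma = 0.1, noise_sigma = 0.05,
                             start_sigma = 0.02, temperature = 300,
                             n_anchors = 20, anchor_radii = c(1, 3),
                             anchors = NULL, seed = 1) {
  mode <- match.arg(mode)
  if (n_per_direction < 1) stop("n_per_direction must be >= 1")
  if (length(directions) * n_per_direction < 2)
    stop("scenario must produce at least 2 trajectories")
  if (v <= 0 || dt <= 0 || K < 2 || spring_k <= 0 || ou_tau <= 0 ||
      temperature <= 0)
    stop("all scales must be positive")
  if (lateral_sigma < 0 || noise_sigma < 0 || start_sigma < 0)
    stop("noise scales must be nonnegative")
  dirs <- lapply(directions, function(d) {
    d <- as.numeric(d)
    if (length(d) != 3 || sum(d^2) == 0) stop("directions must be nonzero 3-vectors")
    d
  })
  structure(list(directions = dirs, n_per_direction = n_per_direction,
                 mode = mode, v = v, dt = dt, K = as.integer(K), x0 = x0,
                 spring_k = spring_k, ou_tau = ou_tau,
                 lateral_sigma = lateral_sigma, noise_sigma = noise_sigma,
                 start_sigma = start_sigma, temperature = temperature,
                 n_anchors = as.integer(n_anchors),
                 anchor_radii = anchor_radii, anchors = anchors,
                 seed = as.integer(seed)),
            class = "pathway_scenario")
}

direction_label <- function(d) paste0("(", paste(d, collapse = ","), ")")

# orthonormal basis perpendicular to unit vector u
lateral_basis <- function(u) {
  ref <- if (abs(u[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- c(u[2] * ref[3] - u[3] * ref[2],
          u[3] * ref[1] - u[1] * ref[3],
          u[1] * ref[2] - u[2] * ref[1])
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(u[2] * e1[3] - u[3] * e1[2],
          u[3] * e1[1] - u[1] * e1[3],
          u[1] * e1[2] - u[2] * e1[1])
  rbind(e1, e2)
}

# anchors uniform in a spherical shell; fixed sub-seed derived from the
# scenario seed so the anchor layout is reproducible on its own
generate_anchors <- function(n, radii, seed) {
  with_seed(seed + 104729L, {
    z <- matrix(stats::rnorm(3 * n), n, 3)
    z <- z / sqrt(rowSums(z^2))
    u <- stats::runif(n)
    r <- (radii[1]^3 + u * (radii[2]^3 - radii[1]^3))^(1 / 3)
    z * r
  })
}

#' Generate a ground-truth-labeled synthetic ensemble
#'
#' Realizes a [pathway_scenario]: for each trajectory the ligand point
#' starts at `x0 * u` plus a small random offset and advances so that its
#' displacement along its pathway direction `u` is exactly `v t`
#' (constraint mode) or fluctuates around `v t` as an exact discrete-time
#' Ornstein-Uhlenbeck process with stationary variance
#' `kB T / spring_k` (restraint mode). Perpendicular to `u` the ligand
#' performs a Gaussian random walk. Contact distances are point-to-anchor
#' distances plus `N(0, noise_sigma)` noise, floored at 0. Fully
#' deterministic for a fixed scenario seed.
#'
#' @param scenario A [pathway_scenario].
#' @return A [trajectory_ensemble] with ground-truth direction labels;
#'   the anchor layout is attached as attribute `"anchors"`.
#' @export
generate_ensemble <- function(scenario) {
  stopifnot(inherits(scenario, "pathway_scenario"))
  sc <- scenario
  anchors <- sc$anchors
  if (is.null(anchors))
    anchors <- generate_anchors(sc$n_anchors, sc$anchor_radii, sc$seed)
  anchors <- as.matrix(anchors)
  m <- nrow(anchors)
  contact_labels <- paste0("A:", seq_len(m))
  kbt <- kB * sc$temperature
  trajs <- list()
  labels <- character(0)
  with_seed(sc$seed, {
    for (d in seq_along(sc$directions)) {
      dir_raw <- sc$directions[[d]]
      u <- dir_raw / sqrt(sum(dir_raw^2))
      lat <- lateral_basis(u)
      for (r in seq_len(sc$n_per_direction)) {
        tps <- (seq_len(sc$K) - 1) * sc$dt
        along <- sc$x0 + sc$v * tps
        if (sc$mode == "restraint") {
          # exact discrete-time OU update: step-size independent statistics
          a <- exp(-sc$dt / sc$ou_tau)
          sd_st <- sqrt(kbt / sc$spring_k)
          delta <- numeric(sc$K)
          delta[1] <- stats::rnorm(1, 0, sd_st)
          innov <- stats::rnorm(sc$K - 1, 0, sd_st * sqrt(1 - a^2))
          for (t in seq(2, sc$K)) delta[t] <- a * delta[t - 1] + innov[t - 1]
          along <- along + delta
        }
        step_sd <- sc$lateral_sigma / sqrt(max(sc$K - 1, 1))
        walk <- rbind(0, cbind(cumsum(stats::rnorm(sc$K - 1, 0, step_sd)),
                               cumsum(stats::rnorm(sc$K - 1, 0, step_sd))))
        offset <- stats::rnorm(3, 0, sc$start_sigma)
        pos <- outer(along, u) + walk %*% lat +
          matrix(offset, sc$K, 3, byrow = TRUE)
        d2 <- outer(rowSums(pos^2), rowSums(anchors^2), "+") -
          2 * pos %*% t(anchors)
        d2[d2 < 0] <- 0
        vals <- sqrt(d2)
        if (sc$noise_sigma > 0)
          vals <- vals + matrix(stats::rnorm(sc$K * m, 0, sc$noise_sigma),
                                sc$K, m)
        vals[vals < 0] <- 0
        id <- sprintf("d%d_r%03d", d, r)
        trajs[[id]] <- new_contact_trajectory(vals, dt = sc$dt, traj_id = id,
                                              contact_labels = contact_labels)
        labels <- c(labels, direction_label(dir_raw))
      }
    }
  })
  out <- trajectory_ensemble(unname(trajs), labels = labels)
  attr(out, "anchors") <- anchors
  attr(out, "scenario") <- sc
  out
}

#' Preset scenarios with controlled pathway overlap
#'
#' Three benchmark presets mirroring increasing separation difficulty:
#' `A_like` uses two well-separated pulling directions, (1,1,0) and
#' (1,-1,0) (90 degrees apart); `B_like` uses the more overlapping pair
#' (1,0,1) and (1,-1,0) (60 degrees); `C_like` merges all three
#' directions.
#'
#' @param preset One of `"A_like"`, `"B_like"`, `"C_like"`.
#' @param seed Integer seed.
#' @param ... Further arguments to [pathway_scenario()] (e.g.
#'   `n_per_direction`, `mode`).
#' @return A labeled [trajectory_ensemble].
#' @export
generate_overlapping_sets <- function(preset = c("A_like", "B_like", "C_like"),
                                      seed = 1, ...) {
  preset <- match.arg(preset)
  dirs <- switch(preset,
                 A_like = list(c(1, 1, 0), c(1, -1, 0)),
                 B_like = list(c(1, 0, 1), c(1, -1, 0)),
                 C_like = list(c(1, 1, 0), c(1, 0, 1), c(1, -1, 0)))
  generate_ensemble(pathway_scenario(directions = dirs, seed = seed, ...))
}

#' Generate a Gaussian work ensemble for free-energy recovery tests
#'
#' Realizes the generative model behind the cumulant estimator: each work
#' curve is `W_i(x) = dG_true(x) + W_diss(x) + eta_i(x)` where the noise
#' `eta_i` is built from independent Gaussian increments whose cumulative
#' variance equals exactly `2 kB T W_diss(x)` at every grid point (which
#' requires `W_diss` nondecreasing). [free_energy()] applied to the
#' result recovers `dG_true` up to sampling error.
#'
#' @param deltaG_spec True free-energy profile: numeric vector on
#'   `x_grid` or a function of x, with `dG(x_0) = 0` (kJ/mol).
#' @param wdiss_spec Dissipative work: numeric vector or function,
#'   nonnegative, nondecreasing, `W_diss(x_0) = 0` (kJ/mol).
#' @param temperature Temperature in K.
#' @param n Number of work curves (>= 2).
#' @param x_grid Strictly increasing pulling coordinate (nm).
#' @param seed Integer seed.
#' @return A [work_ensemble]; the generating profiles are attached as
#'   attributes `"deltaG_true"` and `"wdiss_true"`.
#' @export
generate_work_ensemble <- function(deltaG_spec, wdiss_spec, temperature, n,
                                   x_grid, seed = 1) {
  if (n < 2) stop("n must be >= 2")
  if (any(diff(x_grid) <= 0)) stop("x_grid must be strictly increasing")
  ev <- function(spec) if (is.function(spec)) spec(x_grid) else as.numeric(spec)
  dg <- ev(deltaG_spec)
  wd <- ev(wdiss_spec)
  if (length(dg) != length(x_grid) || length(wd) != length(x_grid))
    stop("profile specs must match the grid")
  if (abs(dg[1]) > 1e-9 || abs(wd[1]) > 1e-9)
    stop("profiles must vanish at the first grid point")
  if (any(wd < 0)) stop("wdiss_spec must be nonnegative")
  if (any(diff(wd) < -1e-12)) stop("wdiss_spec must be nondecreasing in x")
  var_target <- 2 * kB * temperature * wd
  inc_sd <- sqrt(pmax(diff(var_target), 0))
  w <- with_seed(seed, {
    eta <- vapply(seq_len(n), function(i)
      c(0, cumsum(stats::rnorm(length(inc_sd), 0, inc_sd))), numeric(length(x_grid)))
    dg + wd + eta
  })
  we <- work_ensemble(x_grid, w, temperature = temperature)
  attr(we, "deltaG_true") <- dg
  attr(we, "wdiss_true") <- wd
  we
}
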