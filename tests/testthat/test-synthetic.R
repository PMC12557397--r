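test_that("generation is byte-identical under a fixed seed", {
  sc <- pathway_scenario(n_per_direction = 3, K = 30, seed = 5)
  e1 <- generate_ensemble(sc)
  e2 <- generate_ensemble(sc)
  expect_identical(lapply(e1$trajectories, `[[`, "values"),
                   lapply(e2$trajectories, `[[`, "values"))
  expect_identical(e1$labels, e2$labels)
  e3 <- generate_ensemble(pathway_scenario(n_per_direction = 3, K = 30,
                                           seed = 6))
  expect_false(identical(e1$trajectories[[1]]$values,
                         e3$trajectories[[1]]$values))
})

test_that("constraint mode gives exactly linear displacement along the pulling direction", {
  sc <- pathway_scenario(n_per_direction = 2, mode = "constraint", K = 50,
                         noise_sigma = 0, lateral_sigma = 0, start_sigma = 0,
                         seed = 7, directions = list(c(1, 0, 0), c(0, 1, 0)))
  ens <- generate_ensemble(sc)
  anchors <- attr(ens, "anchors")
  # distance column for the first anchor must match closed-form geometry:
  # ligand at (x0 + v t) * u exactly
  tps <- (0:49) * sc$dt
  pos <- outer(sc$x0 + sc$v * tps, c(1, 0, 0))
  expected <- sqrt(rowSums(sweep(pos, 2, anchors[1, ])^2))
  expect_equal(unname(ens$trajectories[[1]]$values[, 1]), expected,
               tolerance = 1e-12)
  # displacement along u is exactly v*dt per frame: observe it through a
  # noise-free anchor placed ON the pulling axis
  u <- c(1, 1, 0) / sqrt(2)
  on_axis <- matrix(5 * u, 1, 3)
  sc3 <- pathway_scenario(n_per_direction = 2, mode = "constraint", K = 50,
                          noise_sigma = 0, lateral_sigma = 0, start_sigma = 0,
                          anchors = on_axis, seed = 9,
                          directions = list(c(1, 1, 0)))
  ens3 <- generate_ensemble(sc3)
  d <- ens3$trajectories[[1]]$values[, 1]
  expect_equal(-diff(d), rep(sc3$v * sc3$dt, 49), tolerance = 1e-12)
})

test_that("restraint fluctuations match the OU stationary variance", {
  # anchor on the pulling axis far away: distance = anchor_r - along-coord,
  # so the along-direction OU fluctuation is directly observable
  u <- c(1, 0, 0)
  sc <- pathway_scenario(n_per_direction = 60, mode = "restraint", K = 400,
                         noise_sigma = 0, lateral_sigma = 0, start_sigma = 0,
                         anchors = matrix(50 * u, 1, 3), seed = 10,
                         directions = list(u), v = 0.001)
  ens <- generate_ensemble(sc)
  resid <- vapply(ens$trajectories, function(tr) {
    d <- tr$values[, 1]
    along <- 50 - d - (sc$x0 + sc$v * (0:399) * sc$dt)
    along
  }, numeric(400))
  vhat <- stats::var(as.vector(resid))
  vtheory <- pathsep::kB * sc$temperature / sc$spring_k
  expect_lt(abs(vhat - vtheory) / vtheory, 0.2)
  # increments decorrelate with the configured relaxation time
  ac <- stats::cor(as.vector(resid[-400, ]), as.vector(resid[-1, ]))
  expect_lt(abs(ac - exp(-sc$dt / sc$ou_tau)), 0.1)
})

test_that("lateral excursion accumulates to the configured terminal scale", {
  u <- c(1, 0, 0)
  sc <- pathway_scenario(n_per_direction = 200, mode = "constraint", K = 100,
                         noise_sigma = 0, lateral_sigma = 0.4, start_sigma = 0,
                         anchors = matrix(c(0, 50, 0), 1, 3), seed = 11,
                         directions = list(u))
  ens <- generate_ensemble(sc)
  # distance to a far anchor on +y ~ 50 - y(t); the per-axis walk reaches
  # terminal sd = lateral_sigma at the final frame
  yend <- vapply(ens$trajectories, function(tr) 50 - tr$values[100, 1],
                 numeric(1))
  expect_lt(abs(stats::sd(yend) - sc$lateral_sigma) / sc$lateral_sigma, 0.25)
})

test_that("well-separated directions give a bimodally separated similarity distribution", {
  ens <- generate_overlapping_sets("A_like", seed = 12, n_per_direction = 15)
  s <- to_similarity(distance_matrix(ens, "euclidean"))
  lab <- ens$labels
  within <- s[outer(lab, lab, "==") & upper.tri(s)]
  between <- s[outer(lab, lab, "!=") & upper.tri(s)]
  # two-component separation statistic: gap between the modes dwarfs spread
  sep <- (mean(within) - mean(between)) /
    sqrt((stats::var(within) + stats::var(between)) / 2)
  expect_gt(sep, 3)
})

test_that("presets produce the documented label sets and overlap ordering", {
  a <- generate_overlapping_sets("A_like", seed = 13, n_per_direction = 4,
                                 K = 50)
  expect_equal(length(unique(a$labels)), 2)
  c3 <- generate_overlapping_sets("C_like", seed = 13, n_per_direction = 4,
                                  K = 50)
  expect_equal(length(unique(c3$labels)), 3)
  expect_equal(length(c3), 12)
  # B-like pathways overlap more than A-like: higher median similarity
  med <- function(preset, seed) {
    e <- generate_overlapping_sets(preset, seed = seed, n_per_direction = 8,
                                   K = 80)
    s <- to_similarity(distance_matrix(e, "euclidean"))
    stats::median(s[upper.tri(s)])
  }
  meds <- vapply(1:10, function(sd) med("B_like", sd) - med("A_like", sd),
                 numeric(1))
  expect_gt(mean(meds), 0)
})

test_that("work ensemble generation hits the target mean and variance exactly in expectation", {
  x <- seq(0, 1, length.out = 21)
  # zero dissipation: every curve equals the true profile
  w0 <- generate_work_ensemble(function(x) 30 * x, function(x) 0 * x,
                               temperature = 300, n = 5, x_grid = x,
                               seed = 14)
  expect_equal(w0$works, matrix(30 * x, 21, 5), ignore_attr = TRUE,
               tolerance = 1e-12)
  # variance calibration: pointwise sample variance ~ 2 kB T W_diss
  n <- 2000
  wd <- function(x) 5 * x
  we <- generate_work_ensemble(function(x) 20 * x, wd, temperature = 300,
                               n = n, x_grid = x, seed = 15)
  target <- 2 * pathsep::kB * 300 * wd(x)
  vhat <- apply(we$works, 1, stats::var)
  # chi-square 99.9% band for the sample variance of n Gaussians
  lo <- target * stats::qchisq(0.0005, n - 1) / (n - 1)
  hi <- target * stats::qchisq(0.9995, n - 1) / (n - 1)
  expect_true(all(vhat[-1] >= lo[-1] & vhat[-1] <= hi[-1]))
  expect_error(generate_work_ensemble(function(x) x, function(x) 1 - x,
                                      300, 5, x, 1), "nondecreasing|vanish")
})

test_that("free_energy recovers the generating profile end to end", {
  x <- seq(0, 2, length.out = 26)
  dg <- function(x) 40 * x - 10 * x^2
  wd <- function(x) 6 * x
  n <- 1000
  we <- generate_work_ensemble(dg, wd, temperature = 300, n = n, x_grid = x,
                               seed = 16)
  fe <- free_energy(we)
  kbt <- pathsep::kB * 300
  for (i in seq(2, 26, by = 4)) {
    sigma2 <- 2 * kbt * wd(x[i])
    se <- sqrt(sigma2 / n + (1 / (2 * kbt))^2 * 2 * sigma2^2 / (n - 1))
    expect_lt(abs(fe$deltaG[i] - dg(x[i])), 3 * se)
  }
})
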