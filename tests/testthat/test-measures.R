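test_that("mean Euclidean distance matches hand geometry and rejects unequal K", {
  p <- make_traj(rbind(c(0, 0), c(0, 0)))
  q <- make_traj(rbind(c(3, 4), c(0, 0)))
  expect_equal(mean_euclidean(p, p), 0)
  expect_equal(mean_euclidean(p, q), 2.5)           # mean of {5, 0}
  expect_equal(mean_euclidean(q, p), 2.5)           # symmetry
  r <- make_traj(rbind(c(0, 0), c(0, 0), c(0, 0)))
  expect_error(mean_euclidean(p, r), "equal-length")
  expect_error(mean_euclidean(p, make_traj(matrix(0, 2, 3))), "contacts")
})

test_that("dependent DTW handles identity, duplication and simple series", {
  a <- make_traj(matrix(runif(10), 5, 2))
  expect_equal(dtw_dependent(a, a), 0)
  s1 <- matrix(c(1, 2), 2, 1)
  s2 <- matrix(c(1, 1, 2, 2), 4, 1)
  expect_equal(dtw_dependent(make_traj(s1), make_traj(s2)), 0)
  expect_error(dtw_dependent(a, make_traj(matrix(0, 5, 3))), "contacts")
  # squared option returns the raw cumulative cost
  b <- make_traj(matrix(runif(10), 5, 2))
  expect_equal(dtw_dependent(a, b, squared = TRUE), dtw_dependent(a, b)^2,
               tolerance = 1e-12)
})

test_that("dependent DTW equals exhaustive warping-path enumeration", {
  set.seed(31)
  for (rep in 1:40) {
    ka <- sample(2:7, 1); kb <- sample(2:7, 1); m <- sample(1:3, 1)
    a <- matrix(runif(ka * m), ka, m)
    b <- matrix(runif(kb * m), kb, m)
    expect_equal(dtw_dependent(a, b), oracle_dtw_enum(a, b),
                 tolerance = 1e-10)
    expect_equal(dtw_dependent(b, a), dtw_dependent(a, b), tolerance = 1e-12)
  }
  # the explicit 3x3 example
  expect_equal(dtw_dependent(matrix(c(0, 0, 0), 3, 1),
                             matrix(c(0, 0, 1), 3, 1)),
               oracle_dtw_enum(matrix(0, 3, 1), matrix(c(0, 0, 1), 3, 1)),
               tolerance = 1e-12)
})

test_that("DTW never exceeds the aligned (diagonal-path) cost", {
  set.seed(32)
  for (rep in 1:20) {
    k <- sample(3:10, 1); m <- sample(1:4, 1)
    a <- matrix(runif(k * m), k, m)
    b <- matrix(runif(k * m), k, m)
    aligned <- sqrt(sum(rowSums((a - b)^2)))
    expect_lte(dtw_dependent(a, b), aligned + 1e-12)
  }
})

test_that("Procrustes disparity is zero under similarity transforms", {
  set.seed(33)
  a <- matrix(rnorm(24), 8, 3)
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  b <- 2.5 * a %*% q + matrix(c(1, -1, 3), 8, 3, byrow = TRUE)
  expect_equal(procrustes_distance(a, b, stride = 1), 0, tolerance = 1e-12)
  expect_equal(procrustes_distance(a, a, stride = 1), 0, tolerance = 1e-12)
  expect_error(procrustes_distance(matrix(1, 8, 3), a, stride = 1),
               "degenerate")
})

test_that("Procrustes disparity equals the closed-form SVD oracle and vegan", {
  set.seed(34)
  for (rep in 1:25) {
    k <- sample(4:12, 1); m <- sample(2:4, 1)
    a <- matrix(rnorm(k * m), k, m)
    b <- matrix(rnorm(k * m), k, m)
    expect_equal(procrustes_distance(a, b, stride = 1),
                 oracle_procrustes(a, b), tolerance = 1e-10)
    expect_equal(procrustes_distance(b, a, stride = 1),
                 procrustes_distance(a, b, stride = 1), tolerance = 1e-10)
  }
  skip_if_not_installed("vegan")
  a <- matrix(rnorm(30), 10, 3); b <- matrix(rnorm(30), 10, 3)
  expect_equal(procrustes_distance(a, b, stride = 1),
               vegan::procrustes(a, b, symmetric = TRUE)$ss,
               tolerance = 1e-10)
})

test_that("Procrustes striding keeps every stride-th frame", {
  set.seed(35)
  a <- matrix(rnorm(60), 20, 3)
  b <- matrix(rnorm(60), 20, 3)
  expect_equal(procrustes_distance(a, b, stride = 5),
               procrustes_distance(a[seq(1, 20, 5), ], b[seq(1, 20, 5), ],
                                   stride = 1),
               tolerance = 1e-12)
})

test_that("Wasserstein distance matches sorted-sample and quantile oracles", {
  expect_equal(wasserstein_distance(matrix(c(0, 0), 2, 1),
                                    matrix(c(1, 1), 2, 1)), 1)
  set.seed(36)
  for (rep in 1:25) {
    k <- sample(3:12, 1); m <- sample(1:3, 1)
    a <- matrix(runif(k * m), k, m)
    b <- matrix(runif(k * m), k, m)
    expected <- sum(vapply(seq_len(m), function(j)
      oracle_w1_sorted(a[, j], b[, j]), numeric(1)))
    expect_equal(wasserstein_distance(a, b), expected, tolerance = 1e-12)
  }
  # unequal lengths against the quantile-function oracle
  for (rep in 1:25) {
    a <- matrix(runif(sample(3:9, 1)), ncol = 1)
    b <- matrix(runif(sample(3:9, 1)), ncol = 1)
    expect_equal(wasserstein_distance(a, b), oracle_w1_quantile(a[, 1], b[, 1]),
                 tolerance = 1e-12)
  }
})

test_that("Wasserstein distance is time-permutation invariant and metric-like", {
  set.seed(37)
  a <- matrix(runif(24), 8, 3)
  b <- matrix(runif(24), 8, 3)
  perm <- sample(8)
  expect_equal(wasserstein_distance(a[perm, ], b), wasserstein_distance(a, b),
               tolerance = 1e-12)
  for (rep in 1:60) {
    x <- matrix(runif(6), ncol = 1); y <- matrix(runif(8), ncol = 1)
    z <- matrix(runif(5), ncol = 1)
    expect_lte(wasserstein_distance(x, z),
               wasserstein_distance(x, y) + wasserstein_distance(y, z) + 1e-12)
  }
})

test_that("all measures are symmetric, nonnegative and zero on identical input", {
  set.seed(38)
  a <- make_traj(matrix(runif(30, 0, 2), 10, 3))
  b <- make_traj(matrix(runif(30, 0, 2), 10, 3))
  for (f in list(mean_euclidean, dtw_dependent,
                 function(x, y) procrustes_distance(x, y, stride = 1),
                 wasserstein_distance)) {
    expect_equal(f(a, b), f(b, a), tolerance = 1e-12)
    expect_gte(f(a, b), 0)
    expect_equal(f(a, a), 0, tolerance = 1e-12)
  }
})

test_that("Euclidean distances are invariant under full-rank PCA projection", {
  set.seed(39)
  ens <- make_ens(replicate(4, matrix(runif(40, 0, 2), 10, 4),
                            simplify = FALSE))
  std <- global_standardize(ens)
  proj <- project_pca(std, fit_pca(std))
  for (i in 1:3) {
    d0 <- mean_euclidean(std$trajectories[[i]], std$trajectories[[i + 1]])
    d1 <- mean_euclidean(proj$trajectories[[i]], proj$trajectories[[i + 1]])
    expect_equal(d1, d0, tolerance = 1e-10)
  }
})

test_that("distance_matrix is symmetric with zero diagonal and matches pair calls", {
  set.seed(40)
  mats <- replicate(4, matrix(runif(20, 0, 2), 10, 2), simplify = FALSE)
  ens <- make_ens(mats)
  for (m in c("euclidean", "dtw", "procrustes", "wasserstein")) {
    d <- distance_matrix(ens, m, stride = 2)
    expect_equal(unclass(d), t(unclass(d)), ignore_attr = TRUE)
    expect_equal(diag(d), rep(0, 4), ignore_attr = TRUE)
    expect_equal(attr(d, "measure"), m)
  }
  d <- distance_matrix(make_ens(mats[1:2]), "euclidean")
  expect_equal(d[1, 2], mean_euclidean(mats[[1]], mats[[2]]))
  # identical trajectories give the zero matrix
  dz <- distance_matrix(make_ens(list(mats[[1]], mats[[1]])), "euclidean")
  expect_true(all(dz == 0))
  # a failing pair is named
  uneq <- make_ens(list(matrix(c(0.5, 1), 2, 1), matrix(c(0.5, 1, 1.5), 3, 1)))
  expect_error(distance_matrix(uneq, "euclidean"), "pair \\(t1, t2\\)")
})

test_that("similarity conversion maps distances affinely onto [0, 1]", {
  d <- matrix(c(0, 0, 2, 0, 0, 4, 2, 4, 0), 3)
  s <- to_similarity(d)
  expect_equal(diag(s), rep(1, 3), ignore_attr = TRUE)
  expect_equal(sort(s[upper.tri(s)]), c(0, 0.5, 1))
  expect_equal(unclass(s), t(unclass(s)), ignore_attr = TRUE)
  expect_error(to_similarity(matrix(0, 3, 3)), "no contrast")
  # rank order of pairs is exactly reversed
  set.seed(41)
  dd <- matrix(0, 5, 5)
  dd[upper.tri(dd)] <- runif(10)
  dd <- dd + t(dd)
  ss <- to_similarity(dd)
  expect_equal(order(ss[upper.tri(ss)]), rev(order(dd[upper.tri(dd)])))
})
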