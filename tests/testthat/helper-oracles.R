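# Independent brute-force oracles used to verify the implementation.
# These deliberately take different computational routes than the package.

# exhaustive dependent-DTW: propagate the cumulative cost of EVERY monotone
# warping path (not just the minimum) and take the minimum at the end
oracle_dtw_enum <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  ka <- nrow(a); kb <- nrow(b)
  paths <- vector("list", ka * kb)
  idx <- function(i, j) (j - 1) * ka + i
  for (i in seq_len(ka)) for (j in seq_len(kb)) {
    loc <- sum((a[i, ] - b[j, ])^2)
    prev <- if (i == 1 && j == 1) 0 else c(
      if (i > 1 && j > 1) paths[[idx(i - 1, j - 1)]],
      if (i > 1) paths[[idx(i - 1, j)]],
      if (j > 1) paths[[idx(i, j - 1)]])
    paths[[idx(i, j)]] <- loc + prev
  }
  sqrt(min(paths[[idx(ka, kb)]]))
}

# equal-length 1-D Wasserstein closed form: mean |sorted difference|
oracle_w1_sorted <- function(x, y) mean(abs(sort(x) - sort(y)))

# unequal-length 1-D Wasserstein by quantile-function integration over the
# breakpoints of both empirical inverse CDFs
oracle_w1_quantile <- function(x, y) {
  sx <- sort(x); sy <- sort(y)
  n <- length(sx); m <- length(sy)
  u <- sort(unique(c(seq_len(n) / n, seq_len(m) / m)))
  lo <- c(0, u[-length(u)])
  qa <- sx[ceiling(u * n - 1e-12)]
  qb <- sy[ceiling(u * m - 1e-12)]
  sum(abs(qa - qb) * (u - lo))
}

# orthogonal-Procrustes disparity in closed form: for column-centered
# unit-Frobenius matrices, 1 - (sum of singular values of A^T B)^2
oracle_procrustes <- function(a, b) {
  std <- function(v) {
    v <- sweep(v, 2, colMeans(v))
    v / sqrt(sum(v^2))
  }
  1 - sum(svd(crossprod(std(a), std(b)))$d)^2
}

# CPM objective by direct double loop over ordered pairs
oracle_cpm <- function(s, assignment, gamma) {
  n <- nrow(s)
  total <- 0
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    if (assignment[i] == assignment[j]) total <- total + s[i, j] - gamma
  }
  total
}

# all set partitions of n elements as restricted-growth assignment vectors
enum_partitions <- function(n) {
  out <- list()
  rec <- function(assign, nextid) {
    i <- length(assign) + 1
    if (i > n) {
      out[[length(out) + 1]] <<- assign
      return()
    }
    for (b in seq_len(nextid)) rec(c(assign, b), max(nextid, b + 1))
  }
  rec(integer(0), 1)
  out
}

# mutual information via the entropy identity MI = H(K) + H(C) - H(K,C)
oracle_mi_entropy <- function(k, c) {
  ent <- function(counts) {
    p <- counts[counts > 0] / sum(counts)
    -sum(p * log(p))
  }
  hk <- ent(table(k)); hc <- ent(table(c))
  hkc <- ent(as.vector(table(k, c)))
  hk + hc - hkc
}

# random symmetric similarity matrix with unit diagonal
random_similarity <- function(n) {
  s <- matrix(stats::runif(n * n), n)
  s <- (s + t(s)) / 2
  diag(s) <- 1
  s
}

# small deterministic ensemble builder for unit tests
make_traj <- function(values, id = "t", dt = 1) {
  pathsep::contact_trajectory(as.matrix(values), dt = dt, traj_id = id)
}

make_ens <- function(mats, labels = NULL) {
  trajs <- lapply(seq_along(mats), function(i)
    make_traj(mats[[i]], id = paste0("t", i)))
  pathsep::trajectory_ensemble(trajs, labels = labels)
}
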