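#' Quantile-based resolution selection
#'
#' Candidate resolution parameters for Leiden/CPM clustering are taken
#' from the distribution of pairwise similarities: the median (`Q2`), the
#' third quartile (`Q3`) or their average (`Qmid`). Quantiles are computed
#' over the off-diagonal upper-triangle entries (self-similarities
#' excluded) with linear interpolation between order statistics.
#'
#' @param s A `trajsim` similarity matrix.
#' @param rule One of `"Q2"`, `"Qmid"`, `"Q3"`.
#' @return The resolution gamma in `[0, 1]`.
#' @export
select_gamma <- function(s, rule = c("Q2", "Qmid", "Q3")) {
  rule <- match.arg(rule)
  if (nrow(s) < 2) stop("need at least N = 2 trajectories")
  vals <- s[upper.tri(s)]
  q <- unname(stats::quantile(vals, c(0.5, 0.75), type = 7))
  switch(rule, Q2 = q[1], Q3 = q[2], Qmid = mean(q))
}

#' Constant Potts Model objective
#'
#' `Phi_CPM = sum_c [e_c - gamma * choose(n_c, 2)]`, where `e_c` is the
#' sum of similarities over unordered intra-cluster pairs and `n_c` the
#' cluster size. Singletons contribute 0; the all-singleton partition has
#' objective 0. This evaluator is the authoritative reference for any
#' clustering backend.
#'
#' @param s Similarity matrix.
#' @param assignment Cluster id per trajectory (any atomic vector).
#' @param gamma Resolution parameter.
#' @return The objective value.
#' @export
cpm_objective <- function(s, assignment, gamma) {
  if (length(assignment) != nrow(s))
    stop("assignment length must match the similarity matrix")
  total <- 0
  for (cl in unique(assignment)) {
    idx <- which(assignment == cl)
    nc <- length(idx)
    if (nc < 2) next
    sub <- s[idx, idx]
    ec <- sum(sub[upper.tri(sub)])
    total <- total + ec - gamma * choose(nc, 2)
  }
  total
}

#' Leiden community detection under the Constant Potts Model
#'
#' Clusters trajectories by maximizing the CPM objective on the fully
#' connected weighted graph whose edge weights are the pairwise
#' similarities (no cutoff or sparsification: every pair contributes).
#' The Leiden algorithm (local moving, refinement, aggregation) is run
#' `restarts` times with seed-derived random states and the partition with
#' the best [cpm_objective()] is kept, making the result deterministic for
#' a fixed seed.
#'
#' @param s A `trajsim` similarity matrix.
#' @param gamma Resolution parameter in `[0, 1]`.
#' @param seed Integer seed.
#' @param restarts Number of independent Leiden runs (default 10).
#' @param n_iterations Leiden iterations per run (default 10).
#' @return An object of class `pathway_partition`: list with `assignment`
#'   (character cluster ids `"1", "2", ...` contiguous in order of
#'   decreasing cluster size), `gamma`, `seed`, `objective`, `grouped`
#'   (FALSE), `small_cluster_threshold` (NA until grouping) and `traj_ids`.
#' @export
leiden_cpm <- function(s, gamma, seed = 1, restarts = 10, n_iterations = 10) {
  if (gamma < 0 || gamma > 1) stop("gamma must lie in [0, 1]")
  n <- nrow(s)
  ids <- rownames(s) %||% paste0("t", seq_len(n))
  sm <- as.matrix(s)
  dimnames(sm) <- NULL
  g <- igraph::graph_from_adjacency_matrix(sm, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  best <- NULL
  best_obj <- -Inf
  with_seed(seed, {
    for (r in seq_len(restarts)) {
      cl <- igraph::cluster_leiden(g, objective_function = "CPM",
                                   resolution = gamma,
                                   n_iterations = n_iterations)
      memb <- igraph::membership(cl)
      obj <- cpm_objective(sm, memb, gamma)
      if (obj > best_obj + 1e-12) {
        best_obj <- obj
        best <- memb
      }
    }
  })
  new_partition(relabel_by_size(best), gamma = gamma, seed = seed,
                objective = best_obj, traj_ids = ids)
}

# contiguous character ids "1", "2", ... ordered by decreasing cluster size
# (ties broken by first appearance)
relabel_by_size <- function(assignment) {
  tab <- table(assignment)
  first <- vapply(names(tab), function(l) which(assignment == l)[1], integer(1))
  ord <- names(tab)[order(-as.integer(tab), first)]
  as.character(match(as.character(assignment), ord))
}

new_partition <- function(assignment, gamma, seed, objective, traj_ids,
                          grouped = FALSE, small_cluster_threshold = NA_integer_) {
  structure(list(assignment = as.character(assignment), gamma = gamma,
                 seed = seed, objective = objective, traj_ids = traj_ids,
                 grouped = grouped,
                 small_cluster_threshold = small_cluster_threshold),
            class = "pathway_partition")
}

#' @export
print.pathway_partition <- function(x, ...) {
  tab <- sort(table(x$assignment), decreasing = TRUE)
  cat(sprintf("pathway_partition: %d trajectories, %d clusters (gamma = %.4g, objective = %.4g)\n",
              length(x$assignment), length(tab), x$gamma, x$objective))
  cat("  sizes:", paste(names(tab), tab, sep = ":", collapse = "  "), "\n")
  if (x$grouped)
    cat(sprintf("  small clusters (size <= %d) grouped under '?'\n",
                x$small_cluster_threshold))
  invisible(x)
}

#' Group small clusters under the "?" label
#'
#' Every cluster with `threshold` or fewer members is reassigned to a
#' single reserved pseudo-cluster `"?"`, matching the convention of
#' reporting unresolved small groups together; all other clusters are
#' unchanged.
#'
#' @param partition A `pathway_partition`.
#' @param threshold Maximum size of a cluster to be grouped (default 5;
#'   0 disables grouping).
#' @return The grouped `pathway_partition` (objective unchanged refers to
#'   the ungrouped assignment and is dropped to `NA`).
#' @export
group_small_clusters <- function(partition, threshold = 5) {
  stopifnot(inherits(partition, "pathway_partition"))
  if (threshold < 0) stop("threshold must be >= 0")
  a <- partition$assignment
  tab <- table(a)
  small <- names(tab)[tab <= threshold]
  if (length(small) > 0) a[a %in% small] <- "?"
  keep <- a != "?"
  if (any(keep)) a[keep] <- relabel_by_size(a[keep])
  new_partition(a, gamma = partition$gamma, seed = partition$seed,
                objective = if (length(small)) NA_real_ else partition$objective,
                traj_ids = partition$traj_ids, grouped = TRUE,
                small_cluster_threshold = as.integer(threshold))
}

#' Block ordering of a similarity matrix
#'
#' Permutation placing same-cluster trajectories contiguously, clusters in
#' decreasing size order (the `"?"` group last), for block-ordered matrix
#' export and plotting. Within clusters the original order is preserved.
#'
#' @param s Similarity matrix (used only for its dimension).
#' @param partition A `pathway_partition`.
#' @return Integer permutation of `1..N`.
#' @export
block_order <- function(s, partition) {
  stopifnot(inherits(partition, "pathway_partition"))
  a <- partition$assignment
  if (length(a) != nrow(s)) stop("partition does not match the matrix")
  tab <- table(a[a != "?"])
  first <- vapply(names(tab), function(l) which(a == l)[1], integer(1))
  lev <- c(names(tab)[order(-as.integer(tab), first)],
           if (any(a == "?")) "?")
  unlist(lapply(lev, function(l) which(a == l)), use.names = FALSE)
}

# run code with a temporary RNG state derived from seed, restoring the
# caller's state afterwards
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
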