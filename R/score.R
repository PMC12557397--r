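#' Entropy of a partition
#'
#' Shannon entropy (natural log) of the cluster-size distribution:
#' `H = -sum_i (|K_i|/N) log(|K_i|/N)`. Zero for a single cluster.
#'
#' @param assignment Cluster labels, one per element (any atomic vector,
#'   or a `pathway_partition`).
#' @return Entropy in nats.
#' @export
partition_entropy <- function(assignment) {
  a <- assignment_vector(assignment)
  if (length(a) == 0) stop("empty partition")
  p <- as.numeric(table(a)) / length(a)
  -sum(p * log(p))
}

assignment_vector <- function(x) {
  if (inherits(x, "pathway_partition")) x$assignment else as.character(x)
}

#' Mutual information between two partitions
#'
#' `MI = sum_ij (n_ij/N) log(N n_ij / (n_i n_j))` over the contingency
#' table of the two clusterings; empty intersections contribute 0.
#' Natural log; `0 <= MI <= min(H(K), H(C))`.
#'
#' @param k,c Cluster labels over the same element set (vectors or
#'   `pathway_partition`s of equal length).
#' @return Mutual information in nats.
#' @export
mutual_information <- function(k, c) {
  ka <- assignment_vector(k); ca <- assignment_vector(c)
  if (length(ka) != length(ca)) stop("partitions must cover the same elements")
  n <- length(ka)
  tab <- table(ka, ca)
  ni <- rowSums(tab); nj <- colSums(tab)
  mi <- 0
  for (i in seq_len(nrow(tab))) for (j in seq_len(ncol(tab))) {
    nij <- tab[i, j]
    if (nij > 0) mi <- mi + (nij / n) * log(n * nij / (ni[i] * nj[j]))
  }
  max(mi, 0)   # clip tiny negative rounding
}

#' Normalized mutual information
#'
#' `NMI = MI / ((H(K) + H(C)) / 2)`, in `[0, 1]`; 1 for identical
#' clusterings (up to relabeling), 0 for independent ones. Convention for
#' trivial partitions: if both entropies are zero the partitions are
#' identical single clusters and 1 is returned; if exactly one entropy is
#' zero, 0 is returned.
#'
#' When scoring a grouped partition, the `"?"` pseudo-cluster is kept as
#' one cluster by default (it is reported as a single group);
#' `drop_question = TRUE` instead restricts both partitions to elements
#' outside `"?"`.
#'
#' @param k,c Cluster labels over the same element set.
#' @param drop_question Exclude elements assigned to `"?"` in either
#'   partition.
#' @return NMI in `[0, 1]`.
#' @export
nmi <- function(k, c, drop_question = FALSE) {
  ka <- assignment_vector(k); ca <- assignment_vector(c)
  if (length(ka) != length(ca)) stop("partitions must cover the same elements")
  if (drop_question) {
    keep <- ka != "?" & ca != "?"
    if (!any(keep)) stop("no elements left after dropping '?'")
    ka <- ka[keep]; ca <- ca[keep]
  }
  hk <- partition_entropy(ka); hc <- partition_entropy(ca)
  if (hk == 0 && hc == 0) return(1)
  if (hk == 0 || hc == 0) return(0)
  mutual_information(ka, ca) / ((hk + hc) / 2)
}

#' Score a clustering against ground truth
#'
#' Convenience wrapper returning NMI together with the mutual information
#' and both entropies as a one-row data frame.
#'
#' @param predicted,truth Cluster labels over the same element set.
#' @param drop_question Passed to [nmi()].
#' @return `data.frame` with columns `nmi`, `mi`, `h_predicted`,
#'   `h_truth`, `n`.
#' @export
score_clustering <- function(predicted, truth, drop_question = FALSE) {
  ka <- assignment_vector(predicted); ca <- assignment_vector(truth)
  data.frame(nmi = nmi(ka, ca, drop_question = drop_question),
             mi = mutual_information(ka, ca),
             h_predicted = partition_entropy(ka),
             h_truth = partition_entropy(ca),
             n = length(ka))
}
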