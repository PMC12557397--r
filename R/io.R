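#' Write a trajectory ensemble to a directory of CSV files
#'
#' One CSV per trajectory (header = contact labels, one row per time step,
#' distances in nm) plus a `manifest.tsv` with columns `traj_id`, `path`
#' (relative), `dt` and optionally `label`. This plain-text dialect
#' round-trips values to storage precision and labels exactly.
#'
#' @param ensemble A [trajectory_ensemble].
#' @param path Directory to write into (created if missing).
#' @param digits Significant digits written (default 17, lossless for
#'   double precision).
#' @return `path`, invisibly.
#' @export
write_ensemble <- function(ensemble, path, digits = 17) {
  stopifnot(inherits(ensemble, "trajectory_ensemble"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  files <- character(length(ensemble))
  for (i in seq_along(ensemble$trajectories)) {
    tr <- ensemble$trajectories[[i]]
    files[i] <- paste0(make.names(tr$traj_id), ".csv")
    df <- as.data.frame(tr$values)
    names(df) <- tr$contact_labels
    df[] <- lapply(df, function(x) sprintf("%.*g", digits, x))
    utils::write.csv(df, file.path(path, files[i]), row.names = FALSE,
                     quote = TRUE)
  }
  manifest <- data.frame(
    traj_id = vapply(ensemble$trajectories, `[[`, character(1), "traj_id"),
    path = files,
    dt = vapply(ensemble$trajectories, `[[`, numeric(1), "dt"),
    stringsAsFactors = FALSE)
  if (!is.null(ensemble$labels)) manifest$label <- ensemble$labels
  utils::write.table(manifest, file.path(path, "manifest.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a trajectory ensemble written by [write_ensemble()]
#'
#' @param path Directory containing `manifest.tsv` and per-trajectory CSVs,
#'   or the path of the manifest file itself.
#' @param validate If `TRUE` (default), entries must be finite and
#'   nonnegative; preprocessed (standardized) ensembles can be read with
#'   `validate = FALSE`.
#' @return A [trajectory_ensemble].
#' @export
read_ensemble <- function(path, validate = TRUE) {
  manifest_path <- if (dir.exists(path)) file.path(path, "manifest.tsv") else path
  if (!file.exists(manifest_path))
    stop("manifest not found: ", manifest_path)
  root <- dirname(manifest_path)
  manifest <- utils::read.table(manifest_path, sep = "\t", header = TRUE,
                                stringsAsFactors = FALSE,
                                colClasses = c(traj_id = "character"))
  trajs <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    df <- utils::read.csv(file.path(root, manifest$path[i]),
                          check.names = FALSE)
    vals <- as.matrix(df)
    if (any(is.na(vals)))
      stop("non-finite entry in ", manifest$path[i])
    maker <- if (validate) contact_trajectory else new_contact_trajectory
    trajs[[i]] <- maker(vals, dt = manifest$dt[i],
                        traj_id = manifest$traj_id[i],
                        contact_labels = colnames(vals))
  }
  labels <- if ("label" %in% names(manifest)) manifest$label else NULL
  trajectory_ensemble(trajs, labels = labels)
}

#' Write / read a distance or similarity matrix as square CSV
#'
#' The matrix is stored with trajectory ids as header row and first column;
#' the measure and preprocessing fingerprint are recorded as `#`-prefixed
#' comment lines for provenance.
#'
#' @param m A matrix of class `trajdist` or `trajsim` (or plain matrix).
#' @param file Output CSV path.
#' @return `file`, invisibly.
#' @export
write_matrix_csv <- function(m, file) {
  con <- file(file, "w")
  on.exit(close(con))
  meta <- attributes(m)
  if (!is.null(meta$measure))
    writeLines(paste0("# measure: ", meta$measure), con)
  if (!is.null(meta$preprocessing))
    writeLines(paste0("# preprocessing: ", meta$preprocessing), con)
  ids <- rownames(m)
  if (is.null(ids)) ids <- paste0("t", seq_len(nrow(m)))
  writeLines(paste(c("id", ids), collapse = ","), con)
  for (i in seq_len(nrow(m)))
    writeLines(paste(c(ids[i], sprintf("%.17g", m[i, ])),
                     collapse = ","), con)
  invisible(file)
}

#' Write / read a pathway partition as TSV
#'
#' Columns `traj_id`, `cluster_id`, `grouped_flag` plus `#`-prefixed
#' header metadata lines (gamma, seed, objective, small-cluster
#' threshold).
#'
#' @param partition A `pathway_partition`.
#' @param file Output TSV path.
#' @return `file`, invisibly.
#' @export
write_partition <- function(partition, file) {
  stopifnot(inherits(partition, "pathway_partition"))
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("# gamma: ", sprintf("%.17g", partition$gamma)),
    paste0("# seed: ", partition$seed),
    paste0("# objective: ", sprintf("%.17g", partition$objective)),
    paste0("# small_cluster_threshold: ", partition$small_cluster_threshold)),
    con)
  df <- data.frame(traj_id = partition$traj_ids,
                   cluster_id = partition$assignment,
                   grouped_flag = partition$assignment == "?")
  utils::write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname write_partition
#' @export
read_partition <- function(file) {
  lines <- readLines(file)
  meta <- grep("^#", lines, value = TRUE)
  body <- lines[!grepl("^#", lines)]
  getm <- function(key) {
    x <- sub(paste0("^# ", key, ": "), "",
             grep(paste0("^# ", key, ":"), meta, value = TRUE))
    if (length(x)) x else NA
  }
  df <- utils::read.table(text = paste(body, collapse = "\n"), sep = "\t",
                          header = TRUE, stringsAsFactors = FALSE,
                          colClasses = c(traj_id = "character",
                                         cluster_id = "character"))
  new_partition(df$cluster_id,
                gamma = as.numeric(getm("gamma")),
                seed = suppressWarnings(as.integer(getm("seed"))),
                objective = as.numeric(getm("objective")),
                traj_ids = df$traj_id,
                grouped = any(df$grouped_flag),
                small_cluster_threshold =
                  suppressWarnings(as.integer(getm("small_cluster_threshold"))))
}

#' @rdname write_matrix_csv
#' @export
read_matrix_csv <- function(file) {
  lines <- readLines(file)
  meta <- grep("^#", lines, value = TRUE)
  body <- lines[!grepl("^#", lines)]
  df <- utils::read.csv(text = paste(body, collapse = "\n"),
                        check.names = FALSE, row.names = 1)
  m <- as.matrix(df)
  measure <- sub("^# measure: ", "", grep("^# measure:", meta, value = TRUE))
  prep <- sub("^# preprocessing: ", "",
              grep("^# preprocessing:", meta, value = TRUE))
  if (length(measure)) attr(m, "measure") <- measure
  if (length(prep)) attr(m, "preprocessing") <- prep
  m
}
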