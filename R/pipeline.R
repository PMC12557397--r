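#' Pipeline run configuration
#'
#' Bundles every knob of the pathway-separation workflow so a run is
#' fully reproducible from its configuration and seed. Serialized as YAML
#' next to the outputs of every run.
#'
#' @param input Path to an ensemble directory/manifest written by
#'   [write_ensemble()], or `NULL` when `synthetic` is given.
#' @param synthetic Optional list describing a synthetic input, e.g.
#'   `list(preset = "A_like", n_per_direction = 40)`; arguments are passed
#'   to [generate_overlapping_sets()].
#' @param preprocess A [preprocess_config] (or list of its arguments).
#' @param measure Similarity measure (see [distance_matrix()]).
#' @param stride Procrustes downsampling stride.
#' @param gamma_rule Resolution rule (see [select_gamma()]).
#' @param seed Integer seed for all randomness in the run.
#' @param small_cluster_threshold Clusters of at most this size are
#'   grouped under `"?"`.
#' @param dctmd Optional list with `works` (path to a work table, first
#'   column x in nm, one column per trajectory), `temperature` (K),
#'   optionally `forces = TRUE` to integrate a force table, and
#'   `min_cluster_size`.
#' @param out_dir Output directory (`NULL`: nothing written).
#' @return An object of class `run_config`.
#' @export
run_config <- function(input = NULL, synthetic = NULL,
                       preprocess = preprocess_config(),
                       measure = "euclidean", stride = 5,
                       gamma_rule = "Q2", seed = 1,
                       small_cluster_threshold = 5,
                       dctmd = NULL, out_dir = NULL) {
  if (is.null(input) && is.null(synthetic))
    stop("either an input path or a synthetic spec is required")
  if (is.list(preprocess) && !inherits(preprocess, "preprocess_config"))
    preprocess <- do.call(preprocess_config, preprocess)
  structure(list(input = input, synthetic = synthetic,
                 preprocess = preprocess, measure = measure, stride = stride,
                 gamma_rule = gamma_rule, seed = as.integer(seed),
                 small_cluster_threshold = small_cluster_threshold,
                 dctmd = dctmd, out_dir = out_dir),
            class = "run_config")
}

#' Read / write a run configuration as YAML
#'
#' @param file YAML path.
#' @param config A [run_config].
#' @return [read_run_config()] returns a `run_config`;
#'   [write_run_config()] returns `file` invisibly.
#' @export
read_run_config <- function(file) {
  raw <- yaml::read_yaml(file)
  raw$preprocess <- do.call(preprocess_config,
                            raw$preprocess %||% list())
  do.call(run_config, raw)
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, file) {
  x <- unclass(config)
  x$preprocess <- unclass(x$preprocess)
  x$preprocess <- x$preprocess[!vapply(x$preprocess, is.null, logical(1))]
  x <- x[!vapply(x, is.null, logical(1))]
  yaml::write_yaml(x, file)
  invisible(file)
}

config_hash <- function(config) {
  # small stable fingerprint of the serialized config (FNV-1a over bytes,
  # 32-bit arithmetic done in doubles to avoid integer overflow)
  xor32 <- function(a, b)
    bitwXor(a %/% 65536, b %/% 65536) * 65536 + bitwXor(a %% 65536, b %% 65536)
  mul32 <- function(a, b)
    ((a %% 65536) * b + ((a %/% 65536) * b %% 65536) * 65536) %% 2^32
  s <- yaml::as.yaml(unclass(config))
  h <- 2166136261
  for (b in utf8ToInt(s)) h <- mul32(xor32(h, b), 16777619)
  sprintf("%04x%04x", h %/% 65536, h %% 65536)
}

#' Run the full pathway-separation pipeline
#'
#' Executes, in order: input (read or synthesize the ensemble),
#' preprocessing, pairwise distance computation, similarity conversion,
#' Leiden/CPM clustering at the quantile-selected resolution,
#' small-cluster grouping, and -- when ground-truth labels and/or work
#' curves are available -- NMI scoring and per-pathway free energies.
#' Identical configuration and seed give identical outputs.
#'
#' @param config A [run_config] or path to its YAML serialization.
#' @param quiet Suppress per-stage progress messages.
#' @return List with elements `ensemble`, `similarity`, `gamma`,
#'   `partition`, and optionally `score` and `profiles`; written to
#'   `config$out_dir` when set (similarity CSV, partition TSV, resolved
#'   config YAML, score TSV, free-energy TSVs), every file stamped with
#'   the config hash.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  say <- function(stage, fmt, ...) {
    if (!quiet) message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
  }
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    say(name, "done in %.2f s", proc.time()[["elapsed"]] - t0)
    out
  }

  ensemble <- stage("input", {
    if (!is.null(config$synthetic)) {
      args <- config$synthetic
      args$seed <- args$seed %||% config$seed
      do.call(generate_overlapping_sets, args)
    } else read_ensemble(config$input)
  })
  say("input", "N = %d trajectories, M = %d contacts", length(ensemble),
      length(ensemble$contact_labels))

  prep <- stage("preprocess", apply_preprocess(ensemble, config$preprocess))
  d <- stage("distances",
             distance_matrix(prep, measure = config$measure,
                             stride = config$stride))
  s <- stage("similarity", to_similarity(d))
  gamma <- select_gamma(s, config$gamma_rule)
  say("cluster", "gamma (%s) = %.4f", config$gamma_rule, gamma)
  partition <- stage("cluster", {
    p <- leiden_cpm(s, gamma, seed = config$seed)
    group_small_clusters(p, config$small_cluster_threshold)
  })

  result <- list(ensemble = ensemble, similarity = s, gamma = gamma,
                 partition = partition)

  if (!is.null(ensemble$labels)) {
    result$score <- stage("score",
                          score_clustering(partition, ensemble$labels))
    say("score", "NMI = %.4f", result$score$nmi)
  }

  if (!is.null(config$dctmd)) {
    result$profiles <- stage("dctmd", {
      dc <- config$dctmd
      tab <- utils::read.table(dc$works, header = TRUE, sep = "\t")
      grid <- tab[[1]]
      mat <- as.matrix(tab[, -1, drop = FALSE])
      we <- if (isTRUE(dc$forces))
        integrate_work(mat, grid, temperature = dc$temperature)
      else work_ensemble(grid, mat, temperature = dc$temperature)
      pathwise_free_energy(we, partition,
                           min_cluster_size = dc$min_cluster_size %||% 100)
    })
  }

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    hash <- config_hash(config)
    tag <- function(f) file.path(config$out_dir, f)
    write_run_config(config, tag(sprintf("config-%s.yaml", hash)))
    write_matrix_csv(s, tag(sprintf("similarity-%s.csv", hash)))
    write_partition(partition, tag(sprintf("partition-%s.tsv", hash)))
    ord <- block_order(s, partition)
    writeLines(as.character(ord), tag(sprintf("block-order-%s.txt", hash)))
    if (!is.null(result$score))
      utils::write.table(result$score, tag(sprintf("score-%s.tsv", hash)),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    for (cl in names(result$profiles))
      write_free_energy(result$profiles[[cl]],
                        tag(sprintf("free-energy-cluster%s-%s.tsv", cl, hash)))
    say("output", "written to %s (config %s)", config$out_dir, hash)
  }
  result
}
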