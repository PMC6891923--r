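#' Run the full reconstruction pipeline and write its artifacts
#'
#' Composes the package end to end: obtain cells (from a synthetic
#' simulation or a directory of pairs files), extract and assemble features,
#' fit the circular trajectory, score it against labels when available, and
#' divide it into substages. All outputs are written as plain-text tables
#' with one JSON sidecar echoing the configuration and its hash.
#'
#' @param config named list. Recognized entries: `seed` (default 1),
#'   `out_dir` (required), `simulate` (list of [sim_spec()] overrides; when
#'   present the input is simulated), `pairs_dir` + `chrom_sizes` +
#'   `bin_width` (read one pairs file per cell instead), `labels` (path to
#'   a label TSV; simulated truth provides labels automatically), `sets`,
#'   `feature_args`, `circlet_args`, `n_stages` (default 12; `0` skips
#'   staging).
#' @return invisibly, a list with `fit`, `scores`, `partition`, `paths`.
#' @export
run_pipeline <- function(config) {
  if (is.null(config$out_dir)) stop("config$out_dir is required")
  seed <- config$seed %||% 1
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  labels <- NULL
  truth <- NULL
  if (!is.null(config$simulate)) {
    spec <- do.call(sim_spec, c(config$simulate, list(seed = seed)))
    sim <- simulate_schic(spec)
    cells <- sim$cells
    truth <- sim$truth
    labels <- setNames(truth$phase, truth$cell_id)
    utils::write.table(truth, file.path(config$out_dir, "truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  } else if (!is.null(config$pairs_dir)) {
    binning <- read_chrom_sizes(config$chrom_sizes, config$bin_width)
    files <- list.files(config$pairs_dir, full.names = TRUE)
    if (!length(files)) stop("no pairs files in ", config$pairs_dir)
    cells <- lapply(files, read_pairs, binning = binning)
  } else stop("config needs either $simulate or $pairs_dir")
  if (!is.null(config$labels)) labels <- read_labels(config$labels)

  Fm <- do.call(extract_features,
                c(list(cells, sets = config$sets %||% c("mcm", "cdd", "pcc")),
                  config$feature_args %||% list()))
  fit <- do.call(circlet, c(list(Fm, seed = seed),
                            config$circlet_args %||% list()))
  tab <- trajectory_table(fit)
  utils::write.table(tab, file.path(config$out_dir, "trajectory.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  scores <- NULL
  if (!is.null(labels)) {
    scores <- evaluate_trajectory(fit, labels)
    utils::write.table(
      data.frame(score = names(scores$scores), value = unname(scores$scores)),
      file.path(config$out_dir, "scores.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }

  partition <- NULL
  n_stages <- config$n_stages %||% 12
  if (n_stages > 0) {
    partition <- tryCatch(
      divide_stages(fit$embedding, fit, n_stages = n_stages,
                    labels = labels, cells = cells),
      error = function(e) {
        warning("staging skipped: ", conditionMessage(e))
        NULL
      })
    if (!is.null(partition))
      utils::write.table(
        data.frame(cell_id = names(partition$stage),
                   stage = as.character(partition$stage)),
        file.path(config$out_dir, "stages.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
  }

  sidecar <- list(config = config, seed = seed,
                  converged = fit$converged, iterations = fit$iterations,
                  n_cells = length(fit$cell_ids),
                  config_hash = config_hash(config))
  jsonlite::write_json(sidecar, file.path(config$out_dir, "run.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(list(fit = fit, scores = scores, partition = partition,
                 paths = config$out_dir))
}

# stable hash of a configuration list (order-normalized JSON -> sum of bytes)
config_hash <- function(config) {
  js <- jsonlite::toJSON(config[order(names(config))], auto_unbox = TRUE,
                         digits = NA, null = "null")
  sprintf("%08x", sum(utf8ToInt(as.character(js)) *
                        (seq_len(nchar(as.character(js))) %% 97 + 1)))
}
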