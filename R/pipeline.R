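## High-level, file-oriented pipeline stages. Each stage is an ordinary R
## function over the module surface (simulate -> extract -> compare ->
## roc); inst/cli/tsp-pipeline.R wraps them for shell use. All stages are
## deterministic given the seed and write a provenance log.

#' Pipeline run configuration
#'
#' Bundles the knobs shared by the pipeline stages. Values mirror the
#' defaults of the underlying functions.
#'
#' @param label_map a [label_map()] or path to a YAML label-map file.
#' @param min_pause_s,trim_edges normalization settings
#'   (see [normalize_timeline()]).
#' @param group_col group column name in feature tables.
#' @param normality_method `"shapiro"` or `"lilliefors"`.
#' @param prune_threshold absolute-correlation threshold for
#'   [prune_correlated()].
#' @param relevance optional explicit relevance order for pruning.
#' @param alpha significance level.
#' @param seed integer seed.
#' @return An object of class `tsp_run_config`.
#' @export
run_config <- function(label_map = speechtsp::label_map(),
                       min_pause_s = 0.03, trim_edges = TRUE,
                       group_col = "group",
                       normality_method = "shapiro",
                       prune_threshold = 0.9, relevance = NULL,
                       alpha = 0.05, seed = 1L) {
  if (is.character(label_map)) label_map <- read_label_map(label_map)
  stopifnot(inherits(label_map, "tsp_label_map"),
            alpha > 0, alpha < 1, min_pause_s >= 0)
  structure(list(label_map = label_map, min_pause_s = min_pause_s,
                 trim_edges = trim_edges, group_col = group_col,
                 normality_method = normality_method,
                 prune_threshold = prune_threshold, relevance = relevance,
                 alpha = alpha, seed = as.integer(seed)),
            class = "tsp_run_config")
}

provenance_log <- function(out_dir, stage, config, extra = list()) {
  cfg_hash <- fnv1a32(paste(deparse(config), collapse = ""))
  log <- c(list(stage = stage,
                timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                seed = config$seed, config_hash = cfg_hash,
                package_version = as.character(utils::packageVersion("speechtsp"))),
           extra)
  yaml::write_yaml(log, file.path(out_dir, sprintf("%s_provenance.yaml", stage)))
  invisible(log)
}

ensure_out_dir <- function(out_dir, force) {
  if (dir.exists(out_dir) && length(list.files(out_dir)) > 0L && !force) {
    stop_speechtsp(sprintf(
      "output directory '%s' exists and is non-empty; use force = TRUE",
      out_dir), "speechtsp_validation_error")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  invisible(out_dir)
}

#' Simulate a cohort to disk
#'
#' Runs [simulate_cohort()] and writes `cohort.ctm`, `features.csv` and a
#' provenance log (seed, config hash) to `out_dir`.
#'
#' @param config a [run_config()].
#' @param n_per_group named counts per group (default `c(control = 31,
#'   aud = 34)`).
#' @param configs generator configs (default [default_configs()]).
#' @param out_dir output directory.
#' @param force overwrite a non-empty `out_dir`.
#' @return The `tsp_cohort`, invisibly.
#' @export
pipeline_simulate <- function(config = run_config(),
                              n_per_group = c(control = 31L, aud = 34L),
                              configs = default_configs(),
                              out_dir, force = FALSE) {
  if (any(n_per_group < 2)) {
    stop_speechtsp("n_per_group must be >= 2 in every group",
                   "speechtsp_validation_error")
  }
  ensure_out_dir(out_dir, force)
  coh <- simulate_cohort(cohort_spec(n_per_group, configs, config$seed))
  write_ctm(coh$timelines, file.path(out_dir, "cohort.ctm"))
  write_feature_table(coh$features, file.path(out_dir, "features.csv"))
  grp <- coh$features[, c("subject_id", "group")]
  utils::write.csv(grp, file.path(out_dir, "groups.csv"), row.names = FALSE)
  provenance_log(out_dir, "simulate", config,
                 list(n_per_group = as.list(n_per_group)))
  invisible(coh)
}

#' Extract features from alignment files
#'
#' Reads every path in `files` (dispatching on extension: `.ctm` via
#' [read_ctm()], `.textgrid` via [read_textgrid()]), normalizes each
#' timeline, computes the temporal parameters and writes `features.csv`.
#' Degenerate inputs (e.g. no phones after normalization) are skipped
#' with a warning; the stage fails only if no timeline survives.
#'
#' @param config a [run_config()].
#' @param files character vector of alignment paths.
#' @param out_dir output directory.
#' @param groups optional named vector mapping subject id to group label.
#' @param tier_name interval tier read from TextGrids (default
#'   `"phones"`).
#' @param force overwrite a non-empty `out_dir`.
#' @return The feature table, invisibly.
#' @export
pipeline_extract <- function(config = run_config(), files, out_dir,
                             groups = NULL, tier_name = "phones",
                             force = FALSE) {
  ensure_out_dir(out_dir, force)
  raw <- list()
  for (f in files) {
    ext <- tolower(sub(".*\\.", "", f))
    new <- if (ext == "ctm") read_ctm(f, config$label_map)
    else if (ext == "textgrid") list(read_textgrid(f, tier_name,
                                                   config$label_map))
    else stop_speechtsp(sprintf("unrecognized alignment extension: %s", f),
                        "speechtsp_validation_error")
    raw <- c(raw, new)
  }
  kept <- list()
  for (tl in raw) {
    norm <- tryCatch(
      normalize_timeline(tl, config$min_pause_s, config$trim_edges),
      speechtsp_degenerate_error = function(e) {
        warning(sprintf("skipping '%s': %s", tl$subject_id,
                        conditionMessage(e)), call. = FALSE)
        NULL
      })
    if (!is.null(norm)) {
      if (!is.null(groups) && norm$subject_id %in% names(groups)) {
        norm$group <- groups[[norm$subject_id]]
      }
      kept[[length(kept) + 1L]] <- norm
    }
  }
  if (length(kept) == 0L) {
    stop_speechtsp("no valid timelines to extract features from",
                   "speechtsp_data_error")
  }
  ft <- build_feature_table(kept)
  write_feature_table(ft, file.path(out_dir, "features.csv"))
  provenance_log(out_dir, "extract", config,
                 list(n_files = length(files), n_subjects = nrow(ft)))
  invisible(ft)
}

#' Group comparison stage
#'
#' Runs [compare_all()] on a features CSV (raw mode) or a summaries CSV
#' (summary mode) and writes `comparison.csv` plus a formatted text
#' report mirroring the usual M/SD/test/d table layout.
#'
#' @param config a [run_config()].
#' @param features_csv path to a feature table (raw mode) or a summary
#'   table with columns variable, n_a, mean_a, sd_a, n_b, mean_b, sd_b
#'   (summary mode).
#' @param out_dir output directory.
#' @param mode `"raw"` or `"summary"`.
#' @param force overwrite a non-empty `out_dir`.
#' @return The comparison table, invisibly.
#' @export
pipeline_compare <- function(config = run_config(), features_csv, out_dir,
                             mode = c("raw", "summary"), force = FALSE) {
  mode <- match.arg(mode)
  if (!file.exists(features_csv)) {
    stop_speechtsp(sprintf("features file not found: %s", features_csv),
                   "speechtsp_data_error")
  }
  ensure_out_dir(out_dir, force)
  tab <- utils::read.csv(features_csv, stringsAsFactors = FALSE)
  if (mode == "raw" && !config$group_col %in% names(tab)) {
    stop_speechtsp(sprintf(
      "feature table lacks the group column '%s'", config$group_col),
      "speechtsp_validation_error")
  }
  cmp <- compare_all(tab, mode = mode, group_col = config$group_col,
                     alpha = config$alpha,
                     normality_method = config$normality_method)
  utils::write.csv(as.data.frame(cmp),
                   file.path(out_dir, "comparison.csv"), row.names = FALSE)
  txt <- file.path(out_dir, "comparison.txt")
  sink(txt); print(cmp); sink()
  provenance_log(out_dir, "compare", config, list(mode = mode))
  invisible(cmp)
}

#' ROC stage: prune, Bonferroni gate, per-variable ROC
#'
#' Runs [prune_correlated()] on the feature table, sets the Bonferroni
#' family size to the kept-set size, runs [roc_batch()] and writes
#' `pruning.csv`, `roc.csv` and per-variable curve coordinates.
#'
#' @param config a [run_config()].
#' @param features_csv path to a per-subject feature table with group
#'   column.
#' @param out_dir output directory.
#' @param m_override optional explicit Bonferroni family size.
#' @param positive which group label is the positive (case) class; by
#'   default the second factor level of the group column.
#' @param force overwrite a non-empty `out_dir`.
#' @return The `tsp_roc_batch`, invisibly.
#' @export
pipeline_roc <- function(config = run_config(), features_csv, out_dir,
                         m_override = NULL, positive = NULL, force = FALSE) {
  if (!file.exists(features_csv)) {
    stop_speechtsp(sprintf("features file not found: %s", features_csv),
                   "speechtsp_data_error")
  }
  ensure_out_dir(out_dir, force)
  ft <- read_feature_table(features_csv)
  if (!config$group_col %in% names(ft)) {
    stop_speechtsp(sprintf(
      "feature table lacks the group column '%s'", config$group_col),
      "speechtsp_validation_error")
  }
  pr <- prune_correlated(ft, threshold = config$prune_threshold,
                         relevance = config$relevance,
                         group_col = config$group_col)
  utils::write.csv(
    data.frame(variable = c(pr$kept, pr$dropped$variable),
               status = rep(c("kept", "dropped"),
                            c(length(pr$kept), nrow(pr$dropped))),
               proxy = c(rep(NA_character_, length(pr$kept)),
                         pr$dropped$proxy),
               r = c(rep(NA_real_, length(pr$kept)), pr$dropped$r)),
    file.path(out_dir, "pruning.csv"), row.names = FALSE)
  m <- m_override %||% length(pr$kept)
  roc <- roc_batch(ft, kept = pr$kept, alpha = config$alpha, m = m,
                   group_col = config$group_col, positive = positive)
  utils::write.csv(as.data.frame(roc), file.path(out_dir, "roc.csv"),
                   row.names = FALSE)
  curves <- attr(roc, "curves")
  curve_df <- do.call(rbind, lapply(names(curves), function(v) {
    cbind(variable = v, curves[[v]])
  }))
  utils::write.csv(curve_df, file.path(out_dir, "roc_curves.csv"),
                   row.names = FALSE)
  provenance_log(out_dir, "roc", config,
                 list(kept = pr$kept, m = m))
  invisible(roc)
}
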