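# CSV/JSON readers and writers for the pipeline artifacts, plus the
# end-to-end driver. CSV dialect: comma-separated, UTF-8, '.' decimal,
# header mandatory; all times in minutes.

trajectory_columns <- c("organoid_id", "treatment", "channel", "time_min",
                        "value")
valid_channels <- c("actin", "damaged_area", "dead_cell_distance")

#' Read a tidy trajectory CSV
#'
#' Validates the schema (required columns, known channel labels, finite
#' numeric values) and returns the table sorted by organoid, channel and
#' time. Schema violations are reported with the offending row numbers.
#'
#' @param path CSV with columns `organoid_id`, `treatment`, `channel`,
#'   `time_min`, `value`.
#' @return Tidy trajectory data frame.
#' @export
read_trajectories <- function(path) {
  stop_if(!file.exists(path), sprintf("no such file: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(trajectory_columns, names(df))
  stop_if(length(missing) > 0,
          paste("missing column(s):", paste(missing, collapse = ", ")))
  bad <- which(!df$channel %in% valid_channels)
  stop_if(length(bad) > 0, sprintf(
    "unknown channel label(s) '%s' at row(s) %s",
    paste(unique(df$channel[bad]), collapse = ", "),
    paste(utils::head(bad, 5), collapse = ", ")))
  for (col in c("time_min", "value")) {
    nn <- which(!is.finite(df[[col]]))
    stop_if(length(nn) > 0, sprintf(
      "non-finite '%s' at row(s) %s", col,
      paste(utils::head(nn, 5), collapse = ", ")))
  }
  df[order(df$organoid_id, df$channel, df$time_min), trajectory_columns]
}

#' Write a tidy trajectory CSV
#'
#' @param trajectories tidy trajectory data frame.
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_trajectories <- function(trajectories, path) {
  stopifnot(all(trajectory_columns %in% names(trajectories)))
  utils::write.csv(trajectories[, trajectory_columns], path,
                   row.names = FALSE)
  invisible(path)
}

#' Write / read a cohort feature table CSV
#'
#' One row per organoid: identifier, treatment, the 13 kinetic features,
#' per-channel SSE diagnostics and the flags string.
#'
#' @param cohort cohort feature table.
#' @param path CSV path.
#' @return The path (write) or the table (read).
#' @export
write_feature_table <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  stop_if(!file.exists(path), sprintf("no such file: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(c("organoid_id", "treatment", feature_names()),
                     names(df))
  stop_if(length(missing) > 0,
          paste("missing column(s):", paste(missing, collapse = ", ")))
  df
}

#' Units sidecar for reported feature tables
#'
#' @param path output CSV path.
#' @return The path, invisibly.
#' @export
write_units_sidecar <- function(path) {
  utils::write.csv(control_reference()[, c("parameter", "unit")], path,
                   row.names = FALSE)
  invisible(path)
}

#' Run the full analysis pipeline on a synthetic or measured dataset
#'
#' Stages: (1) generate a synthetic cohort (or read a trajectory CSV),
#' (2) fit every organoid into the feature table, (3) percent-change chord
#' edges against the control group, (4) PCA and the forest importance
#' report. All artifacts are written under `out_dir` together with a run
#' manifest (seed, configuration, package version) sufficient to regenerate
#' them.
#'
#' @param out_dir output directory (created if needed).
#' @param input optional trajectory CSV path; when `NULL` a synthetic
#'   cohort is generated from `gen_config`.
#' @param gen_config a [generator_config()] (used when `input` is `NULL`).
#' @param fit_cfg a [fit_config()].
#' @param split_cfg a [split_config()].
#' @param control_label control group label.
#' @param seed seed recorded in the manifest and used to derive the stage
#'   seeds.
#' @return Invisible list with the in-memory stage results (`trajectories`,
#'   `cohort`, `pct`, `edges_by_drug`, `edges_by_parameter`, `pca`,
#'   `importance`).
#' @export
run_pipeline <- function(out_dir, input = NULL,
                         gen_config = generator_config(
                           treatments = treatment_presets()),
                         fit_cfg = fit_config(),
                         split_cfg = split_config(),
                         control_label = "control", seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(seed)

  if (is.null(input)) {
    gen_config$seed <- seed
    gen <- generate_cohort(gen_config)
    trajectories <- gen$trajectories
    write_feature_table(gen$truth, file.path(out_dir, "ground_truth.csv"))
  } else {
    trajectories <- read_trajectories(input)
  }
  write_trajectories(trajectories, file.path(out_dir, "trajectories.csv"))

  fit_cfg$seed <- seed + 1L
  cohort <- fit_cohort(trajectories, fit_cfg)
  write_feature_table(cohort, file.path(out_dir, "feature_table.csv"))
  write_units_sidecar(file.path(out_dir, "units.csv"))

  stop_if(!control_label %in% cohort$treatment, sprintf(
    "control group '%s' absent from the fitted cohort", control_label))

  pct <- NULL; edges_drug <- NULL; edges_param <- NULL
  if (length(setdiff(unique(cohort$treatment), control_label)) > 0) {
    pct <- percent_change_table(cohort, control_label)
    utils::write.csv(pct, file.path(out_dir, "percent_change.csv"))
    edges_drug <- max_effects_per_drug(pct)
    edges_param <- max_effects_per_parameter(pct)
    export_chord_edges(edges_drug, file.path(out_dir, "chord_by_drug.csv"))
    export_chord_edges(edges_param,
                       file.path(out_dir, "chord_by_parameter.csv"))
  }

  complete <- cohort[stats::complete.cases(cohort[, feature_names()]), ]
  split_cfg$seed <- seed + 2L
  pca <- run_pca(complete)
  utils::write.csv(pca$loadings, file.path(out_dir, "pca_loadings.csv"))
  utils::write.csv(data.frame(component = seq_along(
    pca$explained_variance_ratio),
    explained_variance_ratio = pca$explained_variance_ratio),
    file.path(out_dir, "pca_variance.csv"), row.names = FALSE)
  report <- importance_report(complete, split_cfg)
  utils::write.csv(importance_table(report),
                   file.path(out_dir, "importance.csv"), row.names = FALSE)

  manifest <- list(
    seed = seed,
    control_label = control_label,
    n_organoids = nrow(cohort),
    n_flagged = sum(nzchar(cohort$flags)),
    fit_config = unclass(fit_cfg),
    split_config = unclass(split_cfg),
    package_version = as.character(utils::packageVersion("restifit")),
    r_version = R.version.string
  )
  if (is.null(input)) {
    gc <- unclass(gen_config)
    gc$grid <- unclass(gc$grid)
    gc$coupling <- if (is.null(gc$coupling)) NULL else unclass(gc$coupling)
    manifest$generator_config <- gc
  }
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(trajectories = trajectories, cohort = cohort, pct = pct,
                 edges_by_drug = edges_drug,
                 edges_by_parameter = edges_param, pca = pca,
                 importance = report))
}
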