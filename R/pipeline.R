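#' Default pipeline configuration
#'
#' Nested list of every pipeline parameter with the study defaults:
#' embedding dimension 2, lag 1, radius 0.1 of the mean pairwise distance
#' (sensitivity pass at 0.01), minimal line length 2, border 2, 30 degC
#' inclusion threshold with 80% exclusion fraction, Satterthwaite intervals,
#' and the synthetic-cohort block.
#'
#' @param input_dir directory with series files, manifest and hormones.
#' @param output_dir directory for result tables.
#' @param seed master seed for simulation.
#' @return nested configuration list.
#' @export
default_pipeline_config <- function(input_dir = "input", output_dir = "output",
                                    seed = 1L) {
  list(paths = list(input_dir = input_dir, output_dir = output_dir),
       embedding = list(dim = 2L, lag = 1L),
       rqa = list(radius_frac = 0.1, lmin = 2L, border = 2L,
                  loi_vertical = TRUE, entropy_base = "natural",
                  sensitivity_radius_frac = NULL),
       preprocess = list(threshold_c = 30, exclusion_fraction = 0.80),
       stats = list(ci = "satterthwaite", standardize_hormone_metric = TRUE,
                    analytes = c("leptin", "adiponectin", "cortisol"),
                    hormone_metrics = c("REC", "DET", "LAM", "ENT", "DIV",
                                        "TRE", "Lmean", "Vmean", "PC1")),
       simulate = list(n_subjects = 14L, series_length = 1440L),
       seed = as.integer(seed))
}

#' Read a pipeline configuration from YAML
#'
#' Values present in the file override the defaults of
#' [default_pipeline_config()]; everything else keeps its default.
#'
#' @param path YAML file.
#' @return nested configuration list.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path))
  user <- yaml::read_yaml(path)
  cfg <- modifyList(default_pipeline_config(), user)
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

.echo_config <- function(config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  config$package_version <- as.character(utils::packageVersion("thermorqa"))
  yaml::write_yaml(config, file.path(dir, "run_manifest.yaml"))
}

#' Stage 1: write a synthetic study cohort
#'
#' Wraps [make_fixture_cohort()] with the pipeline configuration: writes
#' one series file per subject-setting, the manifest, and the hormone table
#' into the configured input directory.
#'
#' @param config pipeline configuration list.
#' @return invisibly, the input directory.
#' @export
pipeline_simulate <- function(config = default_pipeline_config()) {
  sim <- simulation_config(n_subjects = config$simulate$n_subjects,
                           series_length = config$simulate$series_length,
                           seed = config$seed)
  make_fixture_cohort(config$paths$input_dir, sim,
                      rqa_args = c(config$embedding,
                                   config$rqa[c("radius_frac", "lmin", "border")]))
  .echo_config(config, config$paths$input_dir)
  invisible(config$paths$input_dir)
}

# filter + rqa for one on-disk cohort at a given radius
.cohort_pass <- function(manifest, input_dir, config, radius_frac) {
  reports <- list()
  rows <- list()
  for (i in seq_len(nrow(manifest))) {
    for (s in c("urban", "mountainous")) {
      f <- manifest[[paste0(s, "_file")]][i]
      ser <- read_temperature_series(file.path(input_dir, f),
                                     subject_id = manifest$subject_id[i],
                                     setting = s)
      flt <- apply_inclusion_filter(ser,
                                    threshold_c = config$preprocess$threshold_c,
                                    exclusion_fraction = config$preprocess$exclusion_fraction)
      reports[[length(reports) + 1L]] <- flt$report
      if (flt$report$eligible) {
        fit <- rqa(flt$series, dim = config$embedding$dim,
                   lag = config$embedding$lag,
                   radius_frac = radius_frac,
                   lmin = config$rqa$lmin, border = config$rqa$border,
                   loi_vertical = config$rqa$loi_vertical,
                   entropy_base = config$rqa$entropy_base,
                   keep_matrix = "never")
        rows[[length(rows) + 1L]] <- as.data.frame(fit)
      }
    }
  }
  list(reports = do.call(rbind, reports),
       metrics = if (length(rows)) do.call(rbind, rows) else NULL)
}

#' Stage 2: recurrence metrics for every subject-setting
#'
#' Reads the manifest and series files, applies the inclusion filter,
#' runs [rqa()] on each eligible record, and writes `metrics.csv` and
#' `filter_reports.csv` (plus `metrics_sensitivity.csv` when a sensitivity
#' radius is configured). Ineligible subject-settings are listed in the
#' filter report, never silently dropped.
#'
#' @param config pipeline configuration list.
#' @return invisibly, the metrics data frame.
#' @export
pipeline_rqa <- function(config = default_pipeline_config()) {
  input <- config$paths$input_dir
  out <- config$paths$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  manifest <- read_cohort_manifest(file.path(input, "manifest.csv"))
  pass <- .cohort_pass(manifest, input, config, config$rqa$radius_frac)
  write_result_table(pass$reports, file.path(out, "filter_reports.csv"))
  if (is.null(pass$metrics)) stop("no eligible series; nothing to analyse")
  write_result_table(pass$metrics, file.path(out, "metrics.csv"))
  if (!is.null(config$rqa$sensitivity_radius_frac)) {
    sens <- .cohort_pass(manifest, input, config,
                         config$rqa$sensitivity_radius_frac)
    if (!is.null(sens$metrics))
      write_result_table(sens$metrics, file.path(out, "metrics_sensitivity.csv"))
  }
  .echo_config(config, out)
  invisible(pass$metrics)
}

#' Stage 3: statistical analysis of a metrics table
#'
#' Paired setting comparisons for every metric, the PCA composite, the
#' setting mixed-effects models (all metrics plus PC1), and the hormone
#' mixed-effects models (each analyte against each configured metric).
#' Writes `paired_tests.csv`, `pca_summary.csv`, `setting_models.csv` and
#' `hormone_models.csv`. Subjects without both settings are excluded from
#' paired analyses, with their ids returned.
#'
#' @param config pipeline configuration list.
#' @return invisibly, a list with the four result tables and the ids of
#'   unpaired subjects.
#' @export
pipeline_analyze <- function(config = default_pipeline_config()) {
  input <- config$paths$input_dir
  out <- config$paths$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  manifest <- read_cohort_manifest(file.path(input, "manifest.csv"))
  metrics <- read_result_table(file.path(out, "metrics.csv"))
  hormones <- read_hormone_table(file.path(input, "hormones.csv"),
                                 analytes = config$stats$analytes)

  paired_ok <- intersect(metrics$subject_id[metrics$setting == "urban"],
                         metrics$subject_id[metrics$setting == "mountainous"])
  unpaired <- setdiff(unique(metrics$subject_id), paired_ok)
  if (length(unpaired))
    message("excluding unpaired subject(s): ", paste(unpaired, collapse = ", "))
  metrics <- metrics[metrics$subject_id %in% paired_ok, , drop = FALSE]

  pca <- metrics_pca(metrics)
  metrics$PC1 <- pca$scores$PC1[match(paste(metrics$subject_id, metrics$setting),
                                      paste(pca$scores$subject_id,
                                            pca$scores$setting))]
  pca_tab <- data.frame(component = seq_along(pca$eigenvalues),
                        eigenvalue = pca$eigenvalues,
                        prop_var = pca$prop_var)

  all_metrics <- c(.rqa_metric_names, "PC1")
  paired <- do.call(rbind, lapply(all_metrics, function(m)
    paired_metric_test(metrics, m)))
  setting_models <- do.call(rbind, lapply(all_metrics, function(m)
    fit_setting_model(metrics, manifest, m, ci = config$stats$ci)))

  hprep <- prepare_hormones(hormones, config$stats$analytes)
  hm <- list()
  for (a in config$stats$analytes) {
    for (m in config$stats$hormone_metrics) {
      hm[[paste(a, m)]] <- fit_hormone_model(
        hprep, metrics, manifest, a, m,
        standardize = config$stats$standardize_hormone_metric,
        ci = config$stats$ci)
    }
  }
  hormone_models <- do.call(rbind, hm)
  rownames(hormone_models) <- NULL

  write_result_table(paired, file.path(out, "paired_tests.csv"))
  write_result_table(pca_tab, file.path(out, "pca_summary.csv"))
  write_result_table(setting_models, file.path(out, "setting_models.csv"))
  write_result_table(hormone_models, file.path(out, "hormone_models.csv"))
  .echo_config(config, out)
  invisible(list(paired = paired, pca = pca_tab,
                 setting_models = setting_models,
                 hormone_models = hormone_models, unpaired = unpaired))
}

#' Run every pipeline stage
#'
#' Simulate (when no manifest exists in the input directory), compute
#' metrics, analyse.
#'
#' @param config pipeline configuration list.
#' @return invisibly, the [pipeline_analyze()] result list.
#' @export
pipeline_all <- function(config = default_pipeline_config()) {
  if (!file.exists(file.path(config$paths$input_dir, "manifest.csv")))
    pipeline_simulate(config)
  pipeline_rqa(config)
  invisible(pipeline_analyze(config))
}
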