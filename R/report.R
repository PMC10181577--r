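#' Principal component projection of feature vectors
#'
#' Mean-centred PCA (no scaling) via [stats::prcomp()], typically used to
#' visualise the scattering features of the windowed dataset the way the
#' study projects its DWS features.
#'
#' @param vectors Numeric matrix or feature table (metadata columns are
#'   dropped); one row per window.
#' @param n_components Number of leading components (>= 1, <= dimension and
#'   <= number of rows).
#' @param labels Optional class labels carried into the output; defaults to
#'   the `class` column when present.
#' @return An object of class `ae_pca`: list with `scores` (tibble `PC1..`,
#'   plus `class` when labels are known) and `explained_variance`
#'   (fractions of total variance, descending).
#' @export
pca_projection <- function(vectors, n_components = 2, labels = NULL) {
  if (is.null(labels) && "class" %in% colnames(vectors)) {
    labels <- vectors$class
  }
  x <- feature_matrix(vectors)
  if (nrow(x) < 2) abort("Need at least 2 vectors.")
  if (n_components > ncol(x) || n_components > nrow(x)) {
    abort("`n_components` exceeds the data dimension.")
  }
  pc <- prcomp(x, center = TRUE, scale. = FALSE)
  scores <- as_tibble(pc$x[, seq_len(n_components), drop = FALSE])
  if (!is.null(labels)) scores$class <- labels
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  structure(
    list(scores = scores,
         explained_variance = ev[seq_len(n_components)]),
    class = "ae_pca"
  )
}

#' @rdname pca_projection
#' @param object An `ae_pca`.
#' @param ... Unused.
#' @export
autoplot.ae_pca <- function(object, ...) {
  df <- object$scores
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$PC1, y = .data$PC2))
  if ("class" %in% names(df)) {
    p <- p + ggplot2::geom_point(ggplot2::aes(colour = .data$class))
  } else {
    p <- p + ggplot2::geom_point()
  }
  p +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * object$explained_variance[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * object$explained_variance[2])) +
    ggplot2::theme_minimal()
}

#' Configuration of a full experiment run
#'
#' Bundles every stage's settings so a run is reproducible from
#' `(config, seed)` alone. The defaults are desk-scale: the `"desk"` preset
#' (200 kHz sampling), 6 recordings per class of 0.075 s each, 10 windows per
#' recording (1500 samples per window), the default feature bank and
#' scattering configuration, and the 80:20 / 10-fold protocol.
#'
#' @param n_per_class Recordings per class.
#' @param duration Recording length in seconds.
#' @param preset `"desk"` or `"paper"`, see [default_profiles()].
#' @param fs Sampling rate override (Hz).
#' @param difficulty Noise multiplier, see [simulate_dataset()].
#' @param n_windows Windows per recording.
#' @param feature_params A [feature_params()].
#' @param scattering A [scattering_config()].
#' @param protocol An [eval_protocol()] (its seed is set from `seed` at run
#'   time).
#' @param relief_k ReliefF neighbour count.
#' @param pca_classes Optional subset of classes for the PCA projection
#'   (default: all five).
#' @param seed Master seed.
#' @param out_dir Output directory, or `NULL` to skip writing.
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(n_per_class = 6, duration = 0.075,
                              preset = "desk", fs = NULL, difficulty = 1,
                              n_windows = 10,
                              feature_params = aewear::feature_params(),
                              scattering = scattering_config(),
                              protocol = eval_protocol(),
                              relief_k = 10, pca_classes = NULL,
                              seed = 1, out_dir = NULL) {
  structure(
    list(n_per_class = n_per_class, duration = duration, preset = preset,
         fs = fs, difficulty = difficulty, n_windows = n_windows,
         feature_params = feature_params, scattering = scattering,
         protocol = protocol, relief_k = relief_k,
         pca_classes = pca_classes, seed = seed, out_dir = out_dir),
    class = "experiment_config"
  )
}

#' Run the full experiment
#'
#' Executes simulate -> window -> \{handcrafted features, scattering
#' features\} -> twelve-classifier benchmark -> ReliefF ranking -> PCA
#' projection, fully reproducible from the config and its master seed. When
#' `config$out_dir` is set, writes `manifest.csv`, `features.csv`, `dws.csv`,
#' `table2.csv` (12 model rows plus one aggregate row per feature set),
#' `ranking.csv`, `pca.csv` and `run.json` (seed and config hash).
#'
#' @param config An [experiment_config()].
#' @param quiet Suppress per-stage progress messages.
#' @return A list of class `ae_report` with elements `dataset`, `features`,
#'   `dws`, `benchmark`, `relief`, `pca`, `config`, `config_hash`.
#' @export
run_experiment <- function(config = experiment_config(), quiet = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  hash <- rlang::hash(config[setdiff(names(config), "out_dir")])
  say <- function(fmt, ...) {
    if (!quiet) inform(sprintf(paste0("[aewear] ", fmt), ...))
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("Stage '%s' failed (config %s): %s",
                    name, hash, conditionMessage(e)), parent = e)
    })
  }
  t0 <- Sys.time()
  say("simulate: %d recordings/class x %g s (%s preset, difficulty %g)",
      config$n_per_class, config$duration, config$preset, config$difficulty)
  dataset <- stage("simulate", simulate_dataset(
    config$n_per_class, config$duration, fs = config$fs, seed = config$seed,
    preset = config$preset, difficulty = config$difficulty))
  windows <- stage("window", window_dataset(dataset, config$n_windows))
  say("features: %d windows of %d samples", nrow(windows),
      length(windows$samples[[1]]))
  features <- stage("featurebank", feature_table(windows,
                                                 config$feature_params))
  dws <- stage("scatternet",
               scattering_table(windows, config$scattering))
  say("benchmark: 12 models x 2 feature sets")
  protocol <- config$protocol
  protocol$seed <- config$seed
  bench <- stage("benchmark", run_benchmark(features, dws,
                                            protocol = protocol))
  relief <- stage("relief", relieff_weights(features,
                                            k_neighbors = config$relief_k))
  pca_in <- dws
  if (!is.null(config$pca_classes)) {
    pca_in <- dplyr::filter(pca_in, .data$class %in% config$pca_classes)
  }
  pca <- stage("pca", pca_projection(pca_in, 2))
  say("done in %.1f s", as.numeric(difftime(Sys.time(), t0, units = "secs")))
  report <- structure(
    list(dataset = dataset, features = features, dws = dws,
         benchmark = bench, relief = relief, pca = pca, config = config,
         config_hash = hash),
    class = "ae_report"
  )
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

# Table-2-shaped accuracy table: 12 model rows plus one aggregate row per
# feature set, held-out and CV accuracy side by side.
table2 <- function(bench) {
  wide <- tidyr::pivot_wider(
    bench$results, names_from = "feature_set",
    values_from = c("holdout_accuracy", "cv_accuracy"))
  agg <- tidyr::pivot_wider(
    bench$aggregate, names_from = c("feature_set", "metric"),
    values_from = c("mean_accuracy", "std_accuracy"))
  aggrow <- tibble(
    model = "Mean across all models",
    holdout_accuracy_handcrafted = agg$mean_accuracy_handcrafted_holdout_accuracy,
    holdout_accuracy_dws = agg$mean_accuracy_dws_holdout_accuracy,
    cv_accuracy_handcrafted = agg$mean_accuracy_handcrafted_cv_accuracy,
    cv_accuracy_dws = agg$mean_accuracy_dws_cv_accuracy)
  dplyr::bind_rows(wide, aggrow)
}

write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ds <- report$dataset
  manifest <- tibble(
    signal_id = ds$signal_id, class = as.character(ds$class),
    seed = ds$seed,
    duration_s = purrr::map_dbl(ds$signal, ~ length(.x$samples) / .x$fs),
    fs_hz = purrr::map_dbl(ds$signal, "fs"))
  readr::write_csv(manifest, file.path(dir, "manifest.csv"))
  readr::write_csv(report$features, file.path(dir, "features.csv"))
  readr::write_csv(report$dws, file.path(dir, "dws.csv"))
  readr::write_csv(table2(report$benchmark), file.path(dir, "table2.csv"))
  readr::write_csv(tidy(report$relief), file.path(dir, "ranking.csv"))
  pca_df <- report$pca$scores
  pca_df$class <- as.character(pca_df$class)
  readr::write_csv(pca_df, file.path(dir, "pca.csv"))
  jsonlite::write_json(
    list(seed = report$config$seed, config_hash = report$config_hash,
         n_windows_total = nrow(report$features),
         explained_variance = report$pca$explained_variance,
         r_version = as.character(getRversion())),
    file.path(dir, "run.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @export
print.ae_report <- function(x, ...) {
  cat(sprintf("<ae_report: %d windows, config %s>\n",
              nrow(x$features), x$config_hash))
  print(x$benchmark)
  invisible(x)
}
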