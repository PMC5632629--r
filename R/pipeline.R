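#' Run the full dive-analysis pipeline on one deployment
#'
#' Chains the stages: dive detection, phase segmentation with shoulder
#' refinement, location assignment, metric computation, transformation and
#' outlier screening, PCA + Ward clustering with rule-based type naming,
#' per-type quartiles, and per-whale activity budget.
#'
#' @param series A [depth_series()].
#' @param fixes GPS fix table (`time`, `lon`, `lat`).
#' @param grid A `bathy_grid` (or NULL; DistToSeaFlr then missing and the
#'   PCA runs on the remaining complete columns).
#' @param cfg A [detection_config()].
#' @param k_clusters Number of dive types (default 6).
#' @param variance_target PCA variance fraction (default 0.85).
#' @param outlier_k MAD multiplier for outlier screening (NULL skips).
#' @return A list of class `dive_analysis`: `dives`, `phases`, `located`,
#'   `metrics` (all detected dives), `model` (the [dive_type_model()]),
#'   `typed` (metric rows used in clustering, with `type`), `budget`.
#' @export
run_dive_pipeline <- function(series, fixes, grid = NULL,
                              cfg = detection_config(), k_clusters = 6,
                              variance_target = 0.85, outlier_k = 5) {
  dives <- detect_dives(series, cfg)
  if (nrow(dives) == 0) stop("no dives detected")
  phases <- segment_dives(series, dives, cfg)
  located <- assign_locations(dives, fixes)
  metrics <- compute_dive_metrics(series, dives, phases, located, grid)
  model <- dive_type_model(metrics, k_clusters = k_clusters,
                           variance_target = variance_target,
                           outlier_k = outlier_k)
  typed <- metrics[model$rows, , drop = FALSE]
  typed$type <- model$type
  budget <- activity_budget(typed)
  structure(list(dives = dives, phases = phases, located = located,
                 metrics = metrics, model = model, typed = typed,
                 budget = budget),
            class = "dive_analysis")
}

#' @export
print.dive_analysis <- function(x, ...) {
  cat(sprintf("<dive_analysis> %d dives detected; %d used in clustering (%d types)\n",
              nrow(x$dives), length(x$model$labels),
              length(unique(x$model$type))))
  tb <- sort(table(x$typed$type), decreasing = TRUE)
  cat(paste(sprintf("  %-14s %d", names(tb), tb), collapse = "\n"), "\n")
  invisible(x)
}
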