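#' Standardize metrics and reduce with PCA
#'
#' Centres and scales each transformed metric column to unit SD, runs a
#' principal components analysis, and retains the smallest number of
#' components whose cumulative variance fraction reaches `variance_target`.
#' Rows with any missing value (e.g. Speed/TA/PDI missing for edge dives,
#' or dives excluded by the 60-min location rule) are dropped first.
#'
#' @param transformed Data frame holding the 12 transformed metric columns.
#' @param variance_target Cumulative variance fraction to retain (default 0.85).
#' @return A list of class `dive_pca`: `scores` (n x k), `rotation` (full
#'   loadings), `center`, `scale`, `variance_fractions` (all columns),
#'   `n_components` (k), `rows` (row indices of `transformed` retained).
#' @export
standardize_and_pca <- function(transformed, variance_target = 0.85) {
  cols <- intersect(metric_names(), names(transformed))
  x <- as.matrix(transformed[, cols, drop = FALSE])
  keep <- stats::complete.cases(x)
  x <- x[keep, , drop = FALSE]
  if (nrow(x) < 2) stop("need at least 2 complete rows")
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    stop("constant column(s): ", paste(cols[sds == 0], collapse = ", "))
  }
  p <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  vf <- p$sdev^2 / sum(p$sdev^2)
  k <- which(cumsum(vf) >= variance_target - 1e-12)[1]
  structure(list(scores = p$x[, seq_len(k), drop = FALSE],
                 rotation = p$rotation, center = p$center, scale = p$scale,
                 variance_fractions = vf, n_components = k,
                 variance_target = variance_target, rows = which(keep)),
            class = "dive_pca")
}

#' Ward hierarchical clustering of PCA scores
#'
#' Agglomerative clustering under Ward's minimum-variance criterion on
#' Euclidean distances (`stats::hclust(method = "ward.D2")`), cut at
#' `k_clusters`.
#'
#' @param scores Numeric matrix (rows = dives).
#' @param k_clusters Number of clusters to cut (default 6).
#' @return A list: `labels` (integer vector), `tree` (the `hclust` object).
#' @export
ward_cluster <- function(scores, k_clusters = 6) {
  scores <- as.matrix(scores)
  if (k_clusters > nrow(scores)) stop("k_clusters exceeds number of points")
  tree <- stats::hclust(stats::dist(scores), method = "ward.D2")
  labels <- if (k_clusters == 1) rep(1L, nrow(scores)) else
    stats::cutree(tree, k = k_clusters)
  list(labels = as.integer(labels), tree = tree)
}

# Jaccard similarity between two index sets.
jaccard_sets <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0) return(NA_real_)
  length(intersect(a, b)) / u
}

#' Bootstrap Jaccard cluster stability
#'
#' clusterboot-style stability assessment: for each of `B` bootstrap
#' resamples (with replacement) the resample is re-clustered, each original
#' cluster is matched to the resample cluster with the highest Jaccard
#' similarity (computed on the distinct points present in the resample,
#' without enforcing a one-to-one assignment), and the per-cluster
#' similarities are averaged over iterations.
#'
#' @param scores Numeric matrix of PCA scores.
#' @param k_clusters Number of clusters.
#' @param B Bootstrap iterations (default 1000).
#' @param seed Random seed for resampling.
#' @return A list of class `stability_report`: `mean_jaccard` (per original
#'   cluster), `B`, `k_clusters`.
#' @export
bootstrap_jaccard <- function(scores, k_clusters = 6, B = 1000, seed = 1) {
  stopifnot(B >= 1)
  scores <- as.matrix(scores)
  n <- nrow(scores)
  base <- ward_cluster(scores, k_clusters)$labels
  orig_sets <- split(seq_len(n), base)
  set.seed(seed)
  acc <- matrix(NA_real_, B, length(orig_sets))
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    lab <- ward_cluster(scores[idx, , drop = FALSE], k_clusters)$labels
    boot_sets <- lapply(split(seq_along(idx), lab),
                        function(s) unique(idx[s]))
    present <- unique(idx)
    for (ci in seq_along(orig_sets)) {
      a <- intersect(orig_sets[[ci]], present)
      if (length(a) == 0) next
      acc[b, ci] <- max(vapply(boot_sets, jaccard_sets, numeric(1), a = a))
    }
  }
  structure(list(mean_jaccard = colMeans(acc, na.rm = TRUE),
                 B = B, k_clusters = k_clusters),
            class = "stability_report")
}

#' Default thresholds for naming the six dive-type clusters
#'
#' Derived from published per-type medians: shallow types have median
#' MaxDepth < 30 m, Short- vs Long-shallow split at 5 min duration; among
#' deep types, Benthic has median DistToSeaFlr < 25 m, V-shaped has median
#' BottFrac <= 0.3, Variable has median SDBottDepth > 40 m, and Mid-water is
#' the remainder. Naming is a post-hoc labelling convenience, not part of
#' the clustering itself.
#'
#' @return Named list of thresholds.
#' @export
naming_thresholds <- function() {
  list(shallow_depth_m = 30, short_dur_min = 5, benthic_dist_m = 25,
       v_bottfrac = 0.3, variable_sd_m = 40)
}

#' Name clusters by their median metrics
#'
#' Applies the decision list of [naming_thresholds()] to per-cluster medians
#' of the raw (untransformed) metrics. If two clusters collide on a name the
#' provisional names are disambiguated with a numeric suffix and a warning
#' is raised, with the per-cluster medians attached as a diagnostic.
#'
#' @param labels Integer cluster labels.
#' @param metrics_raw Raw metric data frame aligned with `labels` (needs
#'   MaxDepth, DiveDur, DistToSeaFlr, BottFrac, SDBottDepth).
#' @param thresholds See [naming_thresholds()].
#' @return Character vector: cluster id -> type name (named by cluster id),
#'   with attribute `medians`.
#' @export
assign_type_names <- function(labels, metrics_raw,
                              thresholds = naming_thresholds()) {
  stopifnot(length(labels) == nrow(metrics_raw))
  ids <- sort(unique(labels))
  med <- function(v, id) stats::median(metrics_raw[[v]][labels == id], na.rm = TRUE)
  meds <- data.frame(cluster = ids,
                     MaxDepth = vapply(ids, function(i) med("MaxDepth", i), 1),
                     DiveDur = vapply(ids, function(i) med("DiveDur", i), 1),
                     DistToSeaFlr = vapply(ids, function(i) med("DistToSeaFlr", i), 1),
                     BottFrac = vapply(ids, function(i) med("BottFrac", i), 1),
                     SDBottDepth = vapply(ids, function(i) med("SDBottDepth", i), 1))
  name_one <- function(r) {
    if (r$MaxDepth < thresholds$shallow_depth_m) {
      if (r$DiveDur < thresholds$short_dur_min) "Short-shallow" else "Long-shallow"
    } else if (!is.na(r$DistToSeaFlr) && r$DistToSeaFlr < thresholds$benthic_dist_m) {
      "Benthic"
    } else if (r$BottFrac <= thresholds$v_bottfrac) {
      "V-shaped"
    } else if (r$SDBottDepth > thresholds$variable_sd_m) {
      "Variable"
    } else "Mid-water"
  }
  nm <- vapply(seq_along(ids), function(i) name_one(meds[i, ]), character(1))
  if (anyDuplicated(nm)) {
    warning("naming rule collision; provisional names returned (see attr 'medians')")
    nm <- make.unique(nm, sep = " #")
  }
  names(nm) <- ids
  attr(nm, "medians") <- meds
  nm
}

#' Per-type quartiles of MaxDepth and DiveDur
#'
#' First/third quartiles and medians of the untransformed maximum depth and
#' dive duration per dive type, computed with the linear-interpolation
#' (type-7) quantile convention. These windows drive the classification of
#' transmitted dive summaries.
#'
#' @param type Character vector of per-dive type names.
#' @param metrics_raw Raw metrics aligned with `type` (MaxDepth, DiveDur).
#' @return Data frame: `type`, `variable`, `q1`, `median`, `q3`.
#' @export
build_type_quantiles <- function(type, metrics_raw) {
  stopifnot(length(type) == nrow(metrics_raw))
  out <- do.call(rbind, lapply(unique(type), function(tp) {
    do.call(rbind, lapply(c("MaxDepth", "DiveDur"), function(v) {
      x <- metrics_raw[[v]][type == tp]
      q <- stats::quantile(x, c(0.25, 0.5, 0.75), na.rm = TRUE, type = 7,
                           names = FALSE)
      data.frame(type = tp, variable = v, q1 = q[1], median = q[2], q3 = q[3])
    }))
  }))
  rownames(out) <- NULL
  out
}

#' Classify a transmitted dive summary against archived type quartiles
#'
#' A summary dive whose maximum depth and duration both fall inside a type's
#' first-to-third-quartile windows is assigned that type; with no candidate
#' it is "Unknown"; with several candidates the type minimising the sum of
#' |value - median| / (Q3 - Q1) over the two variables wins and the result
#' is flagged ambiguous.
#'
#' @param max_depth,duration_min Summary dive values (vectorised).
#' @param quantiles Output of [build_type_quantiles()].
#' @return Data frame: `type` (or "Unknown"), `ambiguous`.
#' @export
classify_summary_dive <- function(max_depth, duration_min, quantiles) {
  qd <- quantiles[quantiles$variable == "MaxDepth", ]
  qt <- quantiles[quantiles$variable == "DiveDur", ]
  stopifnot(all(qd$type == qt$type))
  n <- length(max_depth)
  type <- character(n); amb <- logical(n)
  for (i in seq_len(n)) {
    in_d <- max_depth[i] >= qd$q1 & max_depth[i] <= qd$q3
    in_t <- duration_min[i] >= qt$q1 & duration_min[i] <= qt$q3
    cand <- which(in_d & in_t)
    if (length(cand) == 0) {
      type[i] <- "Unknown"
    } else if (length(cand) == 1) {
      type[i] <- qd$type[cand]
    } else {
      iqr_d <- pmax(qd$q3[cand] - qd$q1[cand], 1e-9)
      iqr_t <- pmax(qt$q3[cand] - qt$q1[cand], 1e-9)
      score <- abs(max_depth[i] - qd$median[cand]) / iqr_d +
        abs(duration_min[i] - qt$median[cand]) / iqr_t
      type[i] <- qd$type[cand[which.min(score)]]
      amb[i] <- TRUE
    }
  }
  data.frame(type = type, ambiguous = amb)
}

#' Fit the full dive-type model
#'
#' Convenience wrapper: transforms raw metrics, standardizes + PCA to the
#' variance target, Ward-clusters the scores, names clusters, and builds
#' per-type quartiles — the complete classification model for a set of
#' archived dives.
#'
#' @param metrics_raw Raw metric table ([compute_dive_metrics()] output).
#' @param k_clusters Number of dive types (default 6; naming rules are
#'   defined for 6).
#' @param variance_target PCA variance fraction to retain.
#' @param spec Transform spec, default [transform_spec()].
#' @param outlier_k MAD multiplier for outlier screening (NULL to skip).
#' @return A list of class `dive_type_model`: `pca`, `clustering`, `labels`
#'   (integer, aligned to retained rows), `type` (names per retained row),
#'   `type_names`, `quantiles`, `rows` (indices into `metrics_raw`).
#' @export
dive_type_model <- function(metrics_raw, k_clusters = 6,
                            variance_target = 0.85, spec = transform_spec(),
                            outlier_k = 5) {
  transformed <- apply_transforms(metrics_raw, spec)
  rows <- seq_len(nrow(transformed))
  if (!is.null(outlier_k)) {
    fl <- flag_outliers(transformed, k = outlier_k)
    rows <- setdiff(rows, fl$removed)
    transformed <- transformed[rows, , drop = FALSE]
  }
  pca <- standardize_and_pca(transformed, variance_target)
  rows <- rows[pca$rows]
  cl <- ward_cluster(pca$scores, k_clusters)
  raw_used <- metrics_raw[rows, , drop = FALSE]
  nm <- assign_type_names(cl$labels, raw_used)
  type <- unname(nm[as.character(cl$labels)])
  qs <- build_type_quantiles(type, raw_used)
  structure(list(pca = pca, clustering = cl, labels = cl$labels, type = type,
                 type_names = nm, quantiles = qs, rows = rows,
                 transform = spec, k_clusters = k_clusters),
            class = "dive_type_model")
}

#' Serialize / restore a dive-type model as JSON
#'
#' Stores the standardization, loadings, retained components, cluster names
#' and per-type quartiles — everything needed to classify new summary dives.
#'
#' @param model A `dive_type_model`.
#' @param path Output (input) file path.
#' @return `write_dive_type_model` the path invisibly;
#'   `read_dive_type_model` a list with the stored fields.
#' @export
write_dive_type_model <- function(model, path) {
  doc <- list(
    center = as.list(model$pca$center), scale = as.list(model$pca$scale),
    rotation = model$pca$rotation, n_components = model$pca$n_components,
    variance_fractions = model$pca$variance_fractions,
    type_names = as.list(model$type_names), quantiles = model$quantiles,
    transform = as.list(model$transform), k_clusters = model$k_clusters)
  jsonlite::write_json(doc, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_dive_type_model
#' @export
read_dive_type_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  doc$quantiles <- as.data.frame(doc$quantiles)
  doc
}
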