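#' The twelve per-dive summary variables
#'
#' Computes, for every detected dive, the standard behavioural variables:
#' maximum depth (MaxDepth, m), dive duration (DiveDur, min), ascent and
#' descent rate (AscRt/DescRt, m/s), bottom-phase duration (BottDur, min),
#' mean and SD of bottom-phase depth (MeanBottDepth/SDBottDepth, m),
#' post-dive interval (PDI, min), bottom fraction (BottFrac =
#' BottDur/DiveDur), distance to seafloor (DistToSeaFlr, m), horizontal
#' speed from the previous dive (Speed, km/hr) and turning angle across the
#' previous/next dives (TA, deg). Rates use the phase-boundary depths as
#' endpoints (descent: dive start to descent end; ascent: ascent start to
#' dive end). SD uses the n-1 denominator; a single-sample bottom phase gets
#' SDBottDepth = 0. The last dive's PDI is missing, as are Speed/TA/
#' DistToSeaFlr where locations are invalid or neighbours missing.
#'
#' @param series A [depth_series()].
#' @param dives Dive table from [detect_dives()].
#' @param phases Phase table from [segment_dives()].
#' @param located Optional: `dives` augmented by [assign_locations()].
#' @param grid Optional `bathy_grid` for DistToSeaFlr.
#' @return A data frame, one row per dive, with the 12 metric columns plus
#'   `dive`, `tag_id`, `start_time` and `spatial_valid`.
#' @export
compute_dive_metrics <- function(series, dives, phases, located = NULL,
                                 grid = NULL) {
  n <- nrow(dives)
  stopifnot(nrow(phases) == n)
  MaxDepth <- dives$max_depth
  DiveDur <- dives$duration_min
  AscRt <- DescRt <- BottDur <- MeanBottDepth <- SDBottDepth <- numeric(n)
  for (i in seq_len(n)) {
    d <- series$depth[dives$start_idx[i]:dives$end_idx[i]]
    de <- phases$descent_end[i]; as_ <- phases$ascent_start[i]
    len <- length(d)
    DescRt[i] <- if (de > 1) (d[de] - d[1]) / (de - 1) else NA_real_
    AscRt[i] <- if (as_ < len) (d[as_] - d[len]) / (len - as_) else NA_real_
    bott <- d[de:as_]
    BottDur[i] <- (as_ - de + 1) / 60  # sample count at 1 Hz, minutes
    MeanBottDepth[i] <- mean(bott)
    SDBottDepth[i] <- if (length(bott) > 1) stats::sd(bott) else 0
  }
  PDI <- c(as.numeric(difftime(dives$start_time[-1], dives$end_time[-n],
                               units = "mins")), NA_real_)
  BottFrac <- BottDur / DiveDur
  Speed <- TA <- DistToSeaFlr <- lon <- lat <- rep(NA_real_, n)
  spatial_valid <- rep(FALSE, n)
  if (!is.null(located)) {
    spatial_valid <- located$spatial_valid
    lon <- located$lon; lat <- located$lat
    if (!is.null(grid)) {
      ok <- spatial_valid
      DistToSeaFlr[ok] <- distance_to_seafloor(MaxDepth[ok], located$lon[ok],
                                               located$lat[ok], grid)
    }
    if (n >= 2) {
      for (i in 2:n) {
        if (spatial_valid[i - 1] && spatial_valid[i]) {
          Speed[i] <- compute_speed(located$lon[i - 1], located$lat[i - 1],
                                    dives$start_time[i - 1],
                                    located$lon[i], located$lat[i],
                                    dives$start_time[i])
        }
      }
    }
    if (n >= 3) {
      for (i in 2:(n - 1)) {
        if (all(spatial_valid[(i - 1):(i + 1)])) {
          TA[i] <- compute_turning_angle(
            located$lon[i - 1], located$lat[i - 1],
            located$lon[i], located$lat[i],
            located$lon[i + 1], located$lat[i + 1])
        }
      }
    }
  }
  data.frame(dive = seq_len(n), tag_id = dives$tag_id,
             start_time = dives$start_time,
             MaxDepth = MaxDepth, DiveDur = DiveDur, AscRt = AscRt,
             DescRt = DescRt, BottDur = BottDur,
             MeanBottDepth = MeanBottDepth, SDBottDepth = SDBottDepth,
             PDI = PDI, BottFrac = BottFrac, DistToSeaFlr = DistToSeaFlr,
             Speed = Speed, TA = TA, lon = lon, lat = lat,
             spatial_valid = spatial_valid)
}

# Names of the 12 metric columns, in canonical order.
metric_names <- function() {
  c("MaxDepth", "DiveDur", "AscRt", "DescRt", "BottDur", "MeanBottDepth",
    "SDBottDepth", "PDI", "BottFrac", "DistToSeaFlr", "Speed", "TA")
}

#' Default per-variable transformations
#'
#' Square root for MaxDepth, AscRt, DescRt, BottDur, MeanBottDepth,
#' SDBottDepth, DistToSeaFlr, Speed and TA; log10 for PDI; identity for
#' DiveDur and BottFrac.
#'
#' @return Named character vector mapping metric name to transform.
#' @export
transform_spec <- function() {
  c(MaxDepth = "sqrt", DiveDur = "identity", AscRt = "sqrt", DescRt = "sqrt",
    BottDur = "sqrt", MeanBottDepth = "sqrt", SDBottDepth = "sqrt",
    PDI = "log10", BottFrac = "identity", DistToSeaFlr = "sqrt",
    Speed = "sqrt", TA = "sqrt")
}

# Smallest admissible PDI (min): back-to-back dives would break log10, so
# PDI is floored at the smallest value observed in field data.
PDI_FLOOR_MIN <- 0.03

#' Apply (or invert) the per-variable transformations
#'
#' PDI is floored at 0.03 min before log10 so back-to-back dives stay
#' finite. Negative inputs to a square-root column are rejected: they
#' violate upstream invariants.
#'
#' @param metrics Data frame holding (a subset of) the 12 metric columns.
#' @param spec Named transform vector, default [transform_spec()].
#' @return The data frame with transformed columns.
#' @export
apply_transforms <- function(metrics, spec = transform_spec()) {
  out <- metrics
  for (v in intersect(names(spec), names(out))) {
    x <- out[[v]]
    out[[v]] <- switch(spec[[v]],
      identity = x,
      sqrt = {
        if (any(x < 0, na.rm = TRUE)) stop("negative input to sqrt column ", v)
        sqrt(x)
      },
      log10 = log10(pmax(x, PDI_FLOOR_MIN)),
      stop("unknown transform ", spec[[v]]))
  }
  out
}

#' @rdname apply_transforms
#' @export
invert_transforms <- function(metrics, spec = transform_spec()) {
  out <- metrics
  for (v in intersect(names(spec), names(out))) {
    x <- out[[v]]
    out[[v]] <- switch(spec[[v]],
                       identity = x, sqrt = x^2, log10 = 10^x,
                       stop("unknown transform ", spec[[v]]))
  }
  out
}

#' Flag univariate outliers on transformed metrics
#'
#' Automated stand-in for manual outlier screening: values beyond
#' median +/- `k` * MAD (MAD with the 1.4826 normal-consistency constant)
#' in any transformed column are flagged. An override list can force
#' specific rows in or out, preserving an analyst's manual decisions.
#'
#' @param transformed Data frame of transformed metrics.
#' @param k MAD multiplier, default 5.
#' @param columns Columns to screen, default the 12 metric columns present.
#' @param override_add,override_remove Row indices to force-flag / unflag.
#' @return List: `kept` (rows not flagged), `flags` (logical matrix),
#'   `removed` (flagged row indices).
#' @export
flag_outliers <- function(transformed, k = 5, columns = NULL,
                          override_add = integer(0),
                          override_remove = integer(0)) {
  stopifnot(nrow(transformed) > 0)
  columns <- columns %||% intersect(metric_names(), names(transformed))
  flags <- matrix(FALSE, nrow(transformed), length(columns),
                  dimnames = list(NULL, columns))
  for (v in columns) {
    x <- transformed[[v]]
    med <- stats::median(x, na.rm = TRUE)
    m <- stats::mad(x, na.rm = TRUE)
    if (is.na(m) || m == 0) next
    flags[, v] <- !is.na(x) & abs(x - med) > k * m
  }
  removed <- which(rowSums(flags) > 0)
  removed <- setdiff(union(removed, override_add), override_remove)
  list(kept = transformed[setdiff(seq_len(nrow(transformed)), removed), ,
                          drop = FALSE],
       flags = flags, removed = removed)
}
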