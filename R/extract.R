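#' Dive-detection configuration
#'
#' Defaults follow the standard archival-tag dive definition for sperm whales:
#' a dive is any submergence lasting longer than 1 min with maximum depth
#' greater than 10 m. The submergence boundary is depth > 1 m (configurable)
#' to be robust to surface sensor noise; 0 m exactly would fragment dives on
#' noisy records. The bottom phase is delimited by the first and last
#' depth-rate sign change, or a 10-s run of zero rate; brief descent/ascent
#' pauses ("shoulders") are relabelled when the normalized-depth ratio to the
#' next, deeper phase end point falls below `shoulder_ratio`.
#'
#' @param surface_threshold Depth (m) above which a sample counts as submerged.
#' @param min_depth Minimum maximum-depth (m) for a submergence to be a dive.
#' @param min_duration Minimum duration (s); a dive must exceed this strictly.
#' @param zero_rate_run Length (s) of a zero-rate run that ends a phase.
#' @param zero_rate_tol Absolute depth rate (m/s) treated as zero
#'   (sensor quantisation makes exact zeros unreliable).
#' @param shoulder_ratio Normalized-depth ratio below which a pause is
#'   relabelled as a shoulder.
#' @return A list of class `detection_config`.
#' @export
detection_config <- function(surface_threshold = 1.0, min_depth = 10,
                             min_duration = 60, zero_rate_run = 10,
                             zero_rate_tol = 0.01, shoulder_ratio = 0.68) {
  stopifnot(surface_threshold > 0, min_depth > 0, min_duration > 0,
            zero_rate_run > 0, shoulder_ratio > 0, shoulder_ratio < 1)
  structure(list(surface_threshold = surface_threshold, min_depth = min_depth,
                 min_duration = min_duration, zero_rate_run = zero_rate_run,
                 zero_rate_tol = zero_rate_tol, shoulder_ratio = shoulder_ratio),
            class = "detection_config")
}

#' Detect dives in a 1-Hz depth series
#'
#' Finds maximal contiguous runs of samples deeper than the surface threshold
#' and keeps those whose duration strictly exceeds `min_duration` seconds and
#' whose maximum depth strictly exceeds `min_depth` metres.
#'
#' @param series A [depth_series()].
#' @param cfg A [detection_config()].
#' @return A data frame, one row per dive, with 1-based inclusive sample
#'   indices `start_idx`/`end_idx` into the series, times, `max_depth` (m) and
#'   `duration_min` (min). Ordered in time, non-overlapping.
#' @export
detect_dives <- function(series, cfg = detection_config()) {
  stopifnot(inherits(series, "depth_series"))
  empty <- data.frame(tag_id = character(), start_idx = integer(),
                      end_idx = integer(), start_time = as.POSIXct(character(), tz = "UTC"),
                      end_time = as.POSIXct(character(), tz = "UTC"),
                      max_depth = numeric(), duration_min = numeric())
  d <- series$depth
  if (length(d) < 2) return(empty)
  r <- rle(d > cfg$surface_threshold)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  sub <- which(r$values)
  if (length(sub) == 0) return(empty)
  s <- starts[sub]; e <- ends[sub]
  dur_s <- e - s + 1L  # samples at 1 Hz
  maxd <- vapply(seq_along(s), function(i) max(d[s[i]:e[i]]), numeric(1))
  keep <- dur_s > cfg$min_duration & maxd > cfg$min_depth
  s <- s[keep]; e <- e[keep]; dur_s <- dur_s[keep]; maxd <- maxd[keep]
  if (length(s) == 0) return(empty)
  data.frame(tag_id = series$tag_id, start_idx = s, end_idx = e,
             start_time = series_time(series, s),
             end_time = series_time(series, e),
             max_depth = maxd, duration_min = dur_s / 60)
}

# Phase end-point candidates in descent orientation: 1-based sample indices
# where the depth rate first turns from positive (descending) to negative, or
# where a run of >= zero_rate_run near-zero rates begins. Rate convention:
# positive rate = depth increasing (descending).
descent_endpoints <- function(depth, cfg) {
  n <- length(depth)
  if (n < 3) return(integer(0))
  r <- diff(depth)
  tol <- cfg$zero_rate_tol
  sgn <- ifelse(r > tol, 1L, ifelse(r < -tol, -1L, 0L))
  # strict sign changes: positive followed (after possible zeros) by negative
  cand <- integer(0)
  last_sign <- 0L
  zero_run <- 0L
  zero_start <- NA_integer_
  for (i in seq_along(sgn)) {
    if (sgn[i] == 0L) {
      if (zero_run == 0L) zero_start <- i
      zero_run <- zero_run + 1L
      if (zero_run == cfg$zero_rate_run && last_sign == 1L) {
        cand <- c(cand, zero_start)
        last_sign <- 0L
      }
    } else {
      zero_run <- 0L
      if (sgn[i] == -1L && last_sign == 1L) cand <- c(cand, i)
      last_sign <- sgn[i]
    }
  }
  sort(unique(cand))
}

#' Partition a dive into descent, bottom and ascent phases
#'
#' The descent ends at the first instance where the depth-rate sign changes
#' from positive to negative or the rate is zero for `zero_rate_run`
#' consecutive seconds; the ascent begins at the last such instance (the same
#' rule applied to the time-reversed profile). If no qualifying instance
#' exists (a strict V), the bottom phase collapses to the single
#' maximum-depth sample.
#'
#' @param depth Depth samples (m) of one dive at 1 Hz.
#' @param cfg A [detection_config()].
#' @return A list with 1-based `descent_end` (first bottom sample),
#'   `ascent_start` (last bottom sample) and NA shoulder slots. The phases
#'   `[1, descent_end)`, `[descent_end, ascent_start]`, `(ascent_start, n]`
#'   partition the dive exactly.
#' @export
segment_phases <- function(depth, cfg = detection_config()) {
  n <- length(depth)
  stopifnot(n >= 3)
  apex <- which.max(depth)
  de_cand <- descent_endpoints(depth, cfg)
  as_cand_rev <- descent_endpoints(rev(depth), cfg)
  de <- if (length(de_cand)) de_cand[1] else apex
  as_ <- if (length(as_cand_rev)) n + 1L - as_cand_rev[1] else apex
  if (de > as_) { de <- apex; as_ <- apex }
  list(descent_end = as.integer(de), ascent_start = as.integer(as_),
       descent_shoulder_idx = NA_integer_, descent_shoulder_depth = NA_real_,
       ascent_shoulder_idx = NA_integer_, ascent_shoulder_depth = NA_real_)
}

# One-sided shoulder refinement in descent orientation. `cur` is the current
# phase end point; `limit` the deepest admissible index (the other phase
# boundary). Returns the refined end point and any shoulder indices passed.
refine_side <- function(depth, cur, limit, cfg) {
  cand <- descent_endpoints(depth, cfg)
  cand <- cand[cand <= limit]
  shoulders <- integer(0)
  max_depth <- max(depth)
  repeat {
    nxt <- cand[cand > cur & depth[cand] > depth[cur]]
    if (length(nxt) == 0) break
    nxt <- nxt[1]
    p1 <- depth[cur] / max_depth
    p2 <- depth[nxt] / max_depth
    if (p1 / p2 < cfg$shoulder_ratio) {
      shoulders <- c(shoulders, cur)
      cur <- nxt
    } else break
  }
  list(end = cur, shoulders = shoulders)
}

#' Relabel descent/ascent shoulders
#'
#' A brief stop at a relatively shallow depth during descent (or ascent) can
#' be mistaken for the bottom-phase boundary. For the descent side, the
#' normalized depth of the current end point (depth / maximum dive depth) is
#' compared with that of the next, deeper candidate end point; if their ratio
#' is below `shoulder_ratio` (default 0.68) the first point is labelled a
#' shoulder and the deeper point becomes the descent end. The mirrored rule
#' applies to the ascent side. The rule iterates to a fixed point, so
#' re-applying it changes nothing.
#'
#' @param depth Depth samples (m) of one dive.
#' @param phases Result of [segment_phases()].
#' @param cfg A [detection_config()].
#' @return An updated phase list; shoulder indices/depths filled when a
#'   relabelling occurred (only the outermost shoulder is recorded).
#' @export
refine_shoulders <- function(depth, phases, cfg = detection_config()) {
  n <- length(depth)
  des <- refine_side(depth, phases$descent_end, phases$ascent_start, cfg)
  phases$descent_end <- des$end
  if (length(des$shoulders)) {
    phases$descent_shoulder_idx <- des$shoulders[1]
    phases$descent_shoulder_depth <- depth[des$shoulders[1]]
  }
  rev_cur <- n + 1L - phases$ascent_start
  rev_limit <- n + 1L - phases$descent_end
  asc <- refine_side(rev(depth), rev_cur, rev_limit, cfg)
  phases$ascent_start <- n + 1L - asc$end
  if (length(asc$shoulders)) {
    idx <- n + 1L - asc$shoulders[1]
    phases$ascent_shoulder_idx <- idx
    phases$ascent_shoulder_depth <- depth[idx]
  }
  phases
}

#' Segment every detected dive of a series
#'
#' Convenience wrapper: runs [segment_phases()] and [refine_shoulders()] on
#' each row of a dive table.
#'
#' @param series A [depth_series()].
#' @param dives Output of [detect_dives()].
#' @param cfg A [detection_config()].
#' @param refine Apply shoulder refinement (default TRUE).
#' @return A data frame, one row per dive: `descent_end`, `ascent_start`
#'   (1-based, relative to dive start) and shoulder columns.
#' @export
segment_dives <- function(series, dives, cfg = detection_config(), refine = TRUE) {
  rows <- lapply(seq_len(nrow(dives)), function(i) {
    d <- series$depth[dives$start_idx[i]:dives$end_idx[i]]
    ph <- segment_phases(d, cfg)
    if (refine) ph <- refine_shoulders(d, ph, cfg)
    as.data.frame(ph)
  })
  out <- do.call(rbind, rows)
  cbind(dive = seq_len(nrow(dives)), out)
}
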