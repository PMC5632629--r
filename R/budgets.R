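#' Per-whale activity budget
#'
#' For each tag: the percentage of dives of each type, and the percentage of
#' tracked time spent making each dive type, where tracked time is the sum
#' of all dive durations and post-dive intervals. The summed post-dive
#' intervals are reported as the percentage of time spent at the surface, so
#' per-type time shares plus the surface share account for 100% of tracked
#' time. A missing final post-dive interval is treated as 0.
#'
#' @param dives Data frame with `tag_id`, `type`, `DiveDur` (min) and `PDI`
#'   (min).
#' @param types Type ordering for the output columns (default the six
#'   standard names present in the data).
#' @return A data frame, one row per tag: `n_dives`, `total_time_days`,
#'   `pct_dives_<type>`, `pct_time_<type>` and `pct_surface`.
#' @export
activity_budget <- function(dives, types = NULL) {
  if (nrow(dives) == 0) return(data.frame())
  types <- types %||% intersect(dive_type_specs()$name, unique(dives$type))
  types <- union(types, unique(dives$type))
  rows <- lapply(unique(dives$tag_id), function(tag) {
    d <- dives[dives$tag_id == tag, , drop = FALSE]
    pdi <- ifelse(is.na(d$PDI), 0, d$PDI)
    denom <- sum(d$DiveDur) + sum(pdi)
    n <- nrow(d)
    out <- data.frame(tag_id = tag, n_dives = n,
                      total_time_days = denom / 1440)
    for (tp in types) {
      sel <- d$type == tp
      out[[paste0("pct_dives_", tp)]] <- 100 * sum(sel) / n
      out[[paste0("pct_time_", tp)]] <- 100 * sum(d$DiveDur[sel]) / denom
    }
    out$pct_surface <- 100 * sum(pdi) / denom
    out
  })
  do.call(rbind, rows)
}

#' Extended surface periods between dives
#'
#' Gaps between consecutive detected dives (no dive deeper than the
#' detection thresholds), flagged when exceeding 30 and 60 min.
#'
#' @param dives Dive table (time-ordered within tag) with `tag_id`,
#'   `start_time`, `end_time`.
#' @param flag_min,long_flag_min Flag thresholds in minutes.
#' @return Data frame: `tag_id`, `start`, `end`, `duration_min`, `over_30`,
#'   `over_60`.
#' @export
find_surface_periods <- function(dives, flag_min = 30, long_flag_min = 60) {
  out <- lapply(unique(dives$tag_id), function(tag) {
    d <- dives[dives$tag_id == tag, , drop = FALSE]
    d <- d[order(d$start_time), , drop = FALSE]
    if (nrow(d) < 2) return(NULL)
    st <- d$end_time[-nrow(d)]
    en <- d$start_time[-1]
    dur <- as.numeric(difftime(en, st, units = "mins"))
    data.frame(tag_id = tag, start = st, end = en, duration_min = dur,
               over_30 = dur > flag_min, over_60 = dur > long_flag_min)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) out <- data.frame(tag_id = character(), duration_min = numeric(),
                                      over_30 = logical(), over_60 = logical())
  out
}

# Lambert azimuthal equal-area projection (spherical, km), centred at
# (lon0, lat0). Forward and inverse.
laea_project <- function(lon, lat, lon0, lat0) {
  rl <- pi / 180
  ph <- lat * rl; ph0 <- lat0 * rl; dl <- (lon - lon0) * rl
  denom <- 1 + sin(ph0) * sin(ph) + cos(ph0) * cos(ph) * cos(dl)
  k <- sqrt(2 / denom)
  list(x = EARTH_RADIUS_KM * k * cos(ph) * sin(dl),
       y = EARTH_RADIUS_KM * k * (cos(ph0) * sin(ph) - sin(ph0) * cos(ph) * cos(dl)))
}

laea_unproject <- function(x, y, lon0, lat0) {
  rl <- pi / 180
  ph0 <- lat0 * rl
  rho <- sqrt(x^2 + y^2)
  c_ <- 2 * asin(clamp(rho / (2 * EARTH_RADIUS_KM), -1, 1))
  lat <- ifelse(rho == 0, lat0,
                asin(cos(c_) * sin(ph0) + y * sin(c_) * cos(ph0) / rho) / rl)
  lon <- lon0 + ifelse(rho == 0, 0,
                       atan2(x * sin(c_),
                             rho * cos(ph0) * cos(c_) - y * sin(ph0) * sin(c_)) / rl)
  list(lon = lon, lat = lat)
}

# Flat-top hexagon axial assignment. `size` is the hexagon circumradius
# (centre-to-vertex, km). Cube-coordinate rounding.
hex_assign <- function(x, y, size) {
  q <- (2 / 3) * x / size
  r <- (-x / 3 + sqrt(3) / 3 * y) / size
  xq <- q; xr <- r; xs <- -q - r
  rq <- round(xq); rr <- round(xr); rs <- round(xs)
  dq <- abs(rq - xq); dr <- abs(rr - xr); ds <- abs(rs - xs)
  fixq <- dq > dr & dq > ds
  fixr <- !fixq & dr > ds
  rq[fixq] <- -rr[fixq] - rs[fixq]
  rr[fixr] <- -rq[fixr] - rs[fixr]
  list(q = as.integer(rq), r = as.integer(rr))
}

hex_center <- function(q, r, size) {
  list(x = size * 1.5 * q, y = size * sqrt(3) * (r + q / 2))
}

#' Hexagonal dive-density grid
#'
#' Projects spatially valid dive locations to a local azimuthal equal-area
#' plane centred at their centroid and bins them into flat-top hexagonal
#' cells of 5-km size, counting dives per cell and type. Binning is a
#' partition: each dive falls in exactly one cell.
#'
#' @param located Data frame with `lon`, `lat`, `type` and (optionally)
#'   `spatial_valid`.
#' @param cell_km Hexagon size (circumradius, km), default 5.
#' @return A data frame `q`, `r` (axial cell coordinates), `lon`, `lat`
#'   (cell centre), `type`, `count`; attribute `center` holds the
#'   projection origin.
#' @export
hex_density <- function(located, cell_km = 5) {
  d <- located
  if ("spatial_valid" %in% names(d)) d <- d[d$spatial_valid, , drop = FALSE]
  d <- d[!is.na(d$lon) & !is.na(d$lat), , drop = FALSE]
  if (nrow(d) == 0) {
    out <- data.frame(q = integer(), r = integer(), lon = numeric(),
                      lat = numeric(), type = character(), count = integer())
    return(out)
  }
  lon0 <- mean(d$lon); lat0 <- mean(d$lat)
  p <- laea_project(d$lon, d$lat, lon0, lat0)
  h <- hex_assign(p$x, p$y, cell_km)
  key <- paste(h$q, h$r, d$type, sep = "|")
  tab <- table(key)
  parts <- strsplit(names(tab), "|", fixed = TRUE)
  q <- as.integer(vapply(parts, `[`, "", 1))
  r <- as.integer(vapply(parts, `[`, "", 2))
  tp <- vapply(parts, `[`, "", 3)
  ctr <- hex_center(q, r, cell_km)
  ll <- laea_unproject(ctr$x, ctr$y, lon0, lat0)
  out <- data.frame(q = q, r = r, lon = ll$lon, lat = ll$lat, type = tp,
                    count = as.integer(tab))
  attr(out, "center") <- c(lon = lon0, lat = lat0)
  out[order(out$type, out$q, out$r), ]
}

#' Day/night labelling
#'
#' Night spans 20:00-07:00 local time, half-open: 20:00 sharp is night,
#' 07:00 sharp is day. Local time is UTC plus a fixed offset (single study
#' area, no DST).
#'
#' @param time POSIXct UTC times.
#' @param utc_offset Hours added to UTC for local time.
#' @param night_start,night_end Local hours bounding the night (wraps
#'   midnight).
#' @return Character vector "day"/"night".
#' @export
diel_label <- function(time, utc_offset = -7, night_start = 20, night_end = 7) {
  local_hr <- (as.numeric(time) / 3600 + utc_offset) %% 24
  ifelse(local_hr >= night_start | local_hr < night_end, "night", "day")
}

#' Descriptive day/night contrasts per dive type
#'
#' Summarises counts and mean maximum depth per tag x type x day/night, and
#' for each type tests the per-tag paired night-minus-day difference in mean
#' MaxDepth with a sign-permutation test (random sign flips of the per-tag
#' differences). Model-based inference (mixed-effects regression) is left to
#' standard packages; this is the descriptive layer.
#'
#' @param dives Data frame with `tag_id`, `type`, `start_time`, `MaxDepth`.
#' @param utc_offset Hours added to UTC for local time.
#' @param B Permutation iterations (default 1000).
#' @param seed Seed for the permutation draws.
#' @return A list: `cells` (per tag x type x diel summary), `contrast` (per
#'   type: n_tags, mean night-day difference, permutation p; p is NA with
#'   fewer than two tags).
#' @export
diel_contrast <- function(dives, utc_offset = -7, B = 1000, seed = 1) {
  d <- dives
  d$diel <- diel_label(d$start_time, utc_offset)
  agg <- stats::aggregate(MaxDepth ~ tag_id + type + diel, data = d,
                          FUN = mean)
  cnt <- stats::aggregate(MaxDepth ~ tag_id + type + diel, data = d,
                          FUN = length)
  names(agg)[4] <- "mean_max_depth"
  agg$n <- cnt$MaxDepth
  set.seed(seed)
  contrast <- do.call(rbind, lapply(unique(agg$type), function(tp) {
    a <- agg[agg$type == tp, ]
    wide <- merge(a[a$diel == "night", c("tag_id", "mean_max_depth")],
                  a[a$diel == "day", c("tag_id", "mean_max_depth")],
                  by = "tag_id", suffixes = c("_night", "_day"))
    diffs <- wide$mean_max_depth_night - wide$mean_max_depth_day
    m <- if (length(diffs)) mean(diffs) else NA_real_
    p <- NA_real_
    if (length(diffs) >= 2) {
      perm <- replicate(B, mean(diffs * sample(c(-1, 1), length(diffs),
                                               replace = TRUE)))
      p <- (sum(abs(perm) >= abs(m)) + 1) / (B + 1)
    }
    data.frame(type = tp, n_tags = length(diffs), mean_night_minus_day = m,
               p_perm = p)
  }))
  list(cells = agg, contrast = contrast)
}
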