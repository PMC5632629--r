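#' Default dive-type templates
#'
#' Median parameters for the six sperm-whale dive types, used by the
#' simulator: Mid-water, Short-shallow, V-shaped, Benthic, Variable and
#' Long-shallow. Depth/duration/post-dive-interval draws are log-normal
#' around these medians with the given multiplicative `dispersion`. The
#' Benthic template ignores its nominal depth and clamps the bottom phase to
#' the local seafloor (within ~5 m); the V-shaped template forces a bottom
#' fraction of at most 0.05 of dive duration.
#'
#' @return A data frame, one row per dive type, with columns `name`,
#'   `median_max_depth` (m), `median_duration` (min),
#'   `median_bottom_fraction`, `bottom_depth_sd` (m), `median_pdi` (min) and
#'   `dispersion`.
#' @export
dive_type_specs <- function() {
  out <- data.frame(
    name = c("Mid-water", "Short-shallow", "V-shaped",
             "Benthic", "Variable", "Long-shallow"),
    median_max_depth = c(340, 16, 290, 456.5, 635, 21.4),
    median_duration  = c(30.3, 2.3, 21.4, 45.8, 33.1, 11.0),
    median_bottom_fraction = c(0.5, 0.05, 0.03, 0.7, 0.5, 0.7),
    bottom_depth_sd  = c(19.4, 0.3, 5.9, 2.5, 60.3, 1.8),
    median_pdi       = c(8.4, 3.9, 7.5, 7.8, 8.0, 6.0),
    dispersion       = 1.25,
    stringsAsFactors = FALSE)
  stopifnot(all(out$median_max_depth > 0),
            all(out$median_bottom_fraction >= 0 & out$median_bottom_fraction <= 1))
  out
}

#' Scenario configuration for the deployment simulator
#'
#' @param n_dives_per_type Dives per type when `type_mix` is NULL (balanced
#'   design); otherwise `6 * n_dives_per_type` dives are drawn from the mix.
#' @param type_mix Optional probability vector over the six types (sums to 1).
#' @param track_speed_mean Mean horizontal speed of the surface track (km/hr).
#' @param track_turn_sd Heading random-walk step (degrees per minute); 0
#'   yields a straight-line track.
#' @param basin_depth,shelf_depth,canyon_amplitude Parametric seafloor (m):
#'   a smooth west-shelf/east-basin ramp plus an optional east-west canyon.
#'   Equal basin and shelf depths with zero canyon give a flat basin.
#' @param fix_success_prob Probability a post-dive Fastloc attempt succeeds.
#' @param seed Integer seed; fully determines the deployment.
#' @param lon0,lat0 Centre of the study area (decimal degrees).
#' @param grid_res,grid_span Bathymetry grid resolution and extent (degrees).
#' @param utc_offset Hours added to UTC for local time.
#' @param start_time Deployment start (POSIXct UTC).
#' @param tag_id Tag identifier.
#' @param specs Dive-type templates, default [dive_type_specs()].
#' @return A list of class `scenario_config`.
#' @export
scenario_config <- function(n_dives_per_type = 200, type_mix = NULL,
                            track_speed_mean = 3.5, track_turn_sd = 25,
                            basin_depth = 900, shelf_depth = 420,
                            canyon_amplitude = 0,
                            fix_success_prob = 0.9, seed = 1,
                            lon0 = -112, lat0 = 27.5,
                            grid_res = 0.02, grid_span = 2.4,
                            utc_offset = -7,
                            start_time = as.POSIXct("2008-06-01 00:00:00", tz = "UTC"),
                            tag_id = "sim1", specs = dive_type_specs()) {
  if (!is.null(type_mix)) {
    stopifnot(length(type_mix) == nrow(specs), all(type_mix >= 0),
              abs(sum(type_mix) - 1) < 1e-8)
  }
  stopifnot(grid_res > 0, grid_span > 0, track_speed_mean > 0,
            fix_success_prob >= 0, fix_success_prob <= 1)
  structure(list(n_dives_per_type = n_dives_per_type, type_mix = type_mix,
                 track_speed_mean = track_speed_mean, track_turn_sd = track_turn_sd,
                 basin_depth = basin_depth, shelf_depth = shelf_depth,
                 canyon_amplitude = canyon_amplitude,
                 fix_success_prob = fix_success_prob, seed = as.integer(seed),
                 lon0 = lon0, lat0 = lat0, grid_res = grid_res,
                 grid_span = grid_span, utc_offset = utc_offset,
                 start_time = as.POSIXct(start_time, tz = "UTC"),
                 tag_id = tag_id, specs = specs),
            class = "scenario_config")
}

#' Generate a parametric bathymetry grid
#'
#' A regular lon/lat grid of seafloor depth (m, positive down): the west edge
#' shoals to half the shelf depth, a smooth ramp connects shelf to basin, and
#' an optional east-west Gaussian canyon deepens the basin mid-grid. The
#' surface is deterministic given the config.
#'
#' @param config A [scenario_config()].
#' @return A list of class `bathy_grid` with strictly increasing `lon`, `lat`
#'   axes and a `depth` matrix (`length(lon)` x `length(lat)`).
#' @export
generate_bathymetry <- function(config) {
  if (config$grid_res <= 0 || config$grid_span <= 0) stop("non-positive grid resolution")
  half <- config$grid_span / 2
  lon <- seq(config$lon0 - half, config$lon0 + half, by = config$grid_res)
  lat <- seq(config$lat0 - half, config$lat0 + half, by = config$grid_res)
  u <- (lon - lon[1]) / (lon[length(lon)] - lon[1])     # 0 west .. 1 east
  v <- (lat - lat[1]) / (lat[length(lat)] - lat[1])
  ramp_x <- clamp((u - 0.15) / 0.3, 0, 1)
  ramp <- ramp_x^2 * (3 - 2 * ramp_x)                   # smoothstep
  base <- config$shelf_depth + (config$basin_depth - config$shelf_depth) * ramp
  if (config$basin_depth != config$shelf_depth) {
    # nearshore shoaling above the shelf (only when a shelf regime exists)
    taper <- clamp(u / 0.15, 0, 1)
    base <- base - 0.5 * config$shelf_depth * (1 - taper)
  }
  depth <- outer(base, rep(1, length(lat)))
  if (config$basin_depth != config$shelf_depth) {
    # broad deterministic relief over the basin (~8% of basin depth) so
    # seafloor-following dives see naturally varying depths; a flat-basin
    # config (basin == shelf) stays exactly constant
    relief <- 0.08 * config$basin_depth *
      outer(ramp * sin(2 * pi * 1.7 * u), cos(2 * pi * 1.3 * v))
    depth <- depth + relief
  }
  if (config$canyon_amplitude != 0) {
    canyon <- config$canyon_amplitude * exp(-(v - 0.5)^2 / (2 * 0.08^2))
    depth <- depth + outer(ramp, canyon)
  }
  depth[depth < 5] <- 5
  structure(list(lon = lon, lat = lat, depth = depth), class = "bathy_grid")
}

#' Seafloor depth at point locations (nearest grid cell)
#'
#' @param grid A `bathy_grid`.
#' @param lon,lat Coordinate vectors (decimal degrees).
#' @return Seafloor depth (m, positive down); NA outside the grid extent.
#' @export
bathy_lookup <- function(grid, lon, lat) {
  res_lon <- grid$lon[2] - grid$lon[1]
  res_lat <- grid$lat[2] - grid$lat[1]
  i <- round((lon - grid$lon[1]) / res_lon) + 1
  j <- round((lat - grid$lat[1]) / res_lat) + 1
  out <- rep(NA_real_, length(lon))
  ok <- !is.na(i) & !is.na(j) & i >= 1 & i <= length(grid$lon) &
    j >= 1 & j <= length(grid$lat)
  out[ok] <- grid$depth[cbind(i[ok], j[ok])]
  out
}

#' Generate a correlated-random-walk surface track
#'
#' Step speeds are log-normal around `track_speed_mean` (clamped to the
#' plausible 0.1-10.9 km/hr envelope for a swimming sperm whale) and the
#' heading performs a Gaussian random walk. A weak homing bias keeps the
#' track over the central basin of the study area.
#'
#' @param config A [scenario_config()].
#' @param duration_hr Track duration (hours).
#' @param dt_s Step interval (s), default 60.
#' @return A data frame `time` (POSIXct UTC), `lon`, `lat`.
#' @export
generate_track <- function(config, duration_hr, dt_s = 60) {
  stopifnot(duration_hr > 0)
  set.seed(config$seed + 1L)
  n <- ceiling(duration_hr * 3600 / dt_s) + 1
  sdlog <- 0.35
  speeds <- stats::rlnorm(n - 1, log(config$track_speed_mean) - sdlog^2 / 2, sdlog)
  speeds <- clamp(speeds, 0.1, 10.9)
  lon <- numeric(n); lat <- numeric(n)
  lon[1] <- config$lon0; lat[1] <- config$lat0
  heading <- stats::runif(1, 0, 360)
  turn <- if (config$track_turn_sd > 0) stats::rnorm(n - 1, 0, config$track_turn_sd) else rep(0, n - 1)
  half <- config$grid_span / 2
  for (i in seq_len(n - 1)) {
    heading <- (heading + turn[i]) %% 360
    # homing bias back toward the centre near the area edge
    if (config$track_turn_sd > 0) {
      doff <- sqrt((lon[i] - config$lon0)^2 + (lat[i] - config$lat0)^2)
      if (doff > 0.45 * half) {
        home <- (atan2(config$lon0 - lon[i], config$lat0 - lat[i]) * 180 / pi) %% 360
        delta <- ((home - heading + 540) %% 360) - 180
        heading <- (heading + 0.35 * delta) %% 360
      }
    }
    step_km <- speeds[i] * dt_s / 3600
    dx <- step_km * sin(heading * pi / 180)
    dy <- step_km * cos(heading * pi / 180)
    lat[i + 1] <- lat[i] + dy / 110.574
    lon[i + 1] <- lon[i] + dx / (111.32 * cos(lat[i] * pi / 180))
  }
  data.frame(time = config$start_time + (seq_len(n) - 1) * dt_s, lon = lon, lat = lat)
}

# Linear interpolation of track position at arbitrary times.
track_position <- function(track, times) {
  tt <- as.numeric(track$time)
  qq <- as.numeric(times)
  data.frame(
    lon = stats::approx(tt, track$lon, qq, rule = 2)$y,
    lat = stats::approx(tt, track$lat, qq, rule = 2)$y)
}

# Draw per-dive scalar parameters for one dive of a given type.
draw_dive_params <- function(spec, seafloor_depth) {
  disp <- spec$dispersion
  md <- rlnorm_med(1, spec$median_max_depth, disp, lower = 10.4)
  dur <- rlnorm_med(1, spec$median_duration, disp, lower = 1.05)
  pdi <- rlnorm_med(1, spec$median_pdi, disp, lower = 0.25)
  bf <- if (spec$name == "V-shaped") stats::runif(1, 0.01, 0.05) else
    clamp(stats::rnorm(1, spec$median_bottom_fraction, 0.06), 0.02, 0.95)
  if (spec$name == "Benthic") md <- seafloor_depth
  md <- min(md, seafloor_depth)
  list(max_depth = md, duration_min = dur, bottom_fraction = bf, pdi_min = pdi)
}

#' Generate a single 1-Hz dive profile
#'
#' Builds a piecewise profile: linear descent, bottom phase with AR(1)
#' Gaussian depth wiggle of marginal sd `bottom_depth_sd`, linear ascent.
#' Benthic profiles track the seafloor from below (within ~5 m); V-shaped
#' profiles have a bottom fraction of at most 0.05.
#'
#' @param spec One row of [dive_type_specs()] (data frame or list).
#' @param seafloor_depth Seafloor depth (m) under the dive.
#' @param params Optional pre-drawn parameters (see details); drawn from
#'   `spec` when NULL.
#' @return A list: `depth` (1-Hz samples, first/last near surface), `label`,
#'   and the drawn `params`.
#' @export
generate_dive_profile <- function(spec, seafloor_depth, params = NULL) {
  spec <- as.list(spec)
  if (is.null(params)) params <- draw_dive_params(spec, seafloor_depth)
  total_s <- max(round(params$duration_min * 60), 63)
  bott_s <- round(total_s * params$bottom_fraction)
  bott_s <- max(min(bott_s, total_s - 20), 1)
  rest <- total_s - bott_s
  desc_s <- max(round(rest * stats::runif(1, 0.45, 0.55)), 3)
  asc_s <- max(rest - desc_s, 3)
  sd_b <- spec$bottom_depth_sd
  if (spec$name == "Benthic") {
    bottom <- seafloor_depth - abs(ar1_noise(bott_s, sd_b, rho = 0.95))
  } else {
    centre <- max(params$max_depth - 1.5 * sd_b, 0.75 * params$max_depth)
    bottom <- clamp(centre + ar1_noise(bott_s, sd_b, rho = 0.95),
                    0.5 * params$max_depth, params$max_depth)
    # the drawn maximum depth is realized exactly (shift preserves the wiggle SD)
    bottom <- bottom + (params$max_depth - max(bottom))
  }
  descent <- seq(0.2, bottom[1], length.out = desc_s + 1)[-(desc_s + 1)]
  ascent <- seq(bottom[bott_s], 0.2, length.out = asc_s + 1)[-1]
  depth <- c(descent, bottom, ascent)
  list(depth = depth, label = spec$name, params = params)
}

#' Generate a complete synthetic tag deployment
#'
#' Dives of the configured type mix are concatenated with surface intervals
#' drawn from each type's post-dive-interval distribution (surface depth
#' noise uniform on [0, 0.5] m). A Fastloc GPS fix is attempted immediately
#' after the whale surfaces from each Qualifying Dive (> 10 min duration and
#' > 10 m depth), succeeding with probability `fix_success_prob`; a second
#' attempt follows 5 min later if the whale has not yet re-submerged below
#' 10 m. Output is fully determined by `config$seed`.
#'
#' @param config A [scenario_config()].
#' @return A list of class `adb_deployment`: `series` ([depth_series()]),
#'   `fixes` (data frame `tag_id`,`time`,`lon`,`lat`), `bathy`
#'   (`bathy_grid`), `truth` (per-dive type label, times, sample indices,
#'   true location and seafloor depth), `track`, and `config`.
#' @export
generate_deployment <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  specs <- config$specs
  set.seed(config$seed)
  if (is.null(config$type_mix)) {
    labels <- sample(rep(specs$name, each = config$n_dives_per_type))
  } else {
    labels <- sample(specs$name, 6L * config$n_dives_per_type,
                     replace = TRUE, prob = config$type_mix)
  }
  n <- length(labels)
  bathy <- generate_bathymetry(config)

  # Pass 1: durations and surface intervals fix the timeline.
  idx <- match(labels, specs$name)
  dur_min <- numeric(n); pdi_min <- numeric(n)
  for (i in seq_len(n)) {
    sp <- as.list(specs[idx[i], ])
    dur_min[i] <- rlnorm_med(1, sp$median_duration, sp$dispersion, lower = 1.05)
    pdi_min[i] <- rlnorm_med(1, sp$median_pdi, sp$dispersion, lower = 0.25)
  }
  lead_s <- 120L
  dur_s <- round(dur_min * 60)
  pdi_s <- round(pdi_min * 60)
  start_s <- lead_s + cumsum(c(0, (dur_s + pdi_s)[-n]))  # provisional offsets
  total_hr <- (lead_s + sum(dur_s + pdi_s) + lead_s) / 3600

  track <- generate_track(config, total_hr)
  pos <- track_position(track, config$start_time + start_s)
  seafloor <- bathy_lookup(bathy, pos$lon, pos$lat)
  seafloor[is.na(seafloor)] <- config$basin_depth

  # Pass 2: profiles (lengths may differ by rounding from pass-1 durations).
  set.seed(config$seed + 2L)
  segs <- vector("list", 2L * n + 2L)
  segs[[1]] <- stats::runif(lead_s, 0, 0.5)
  cursor <- lead_s
  truth <- data.frame(dive = seq_len(n), label = labels,
                      start_idx = NA_integer_, end_idx = NA_integer_,
                      lon = pos$lon, lat = pos$lat, seafloor = seafloor,
                      max_depth = NA_real_, duration_min = NA_real_,
                      bottom_fraction = NA_real_, pdi_min = pdi_min)
  for (i in seq_len(n)) {
    sp <- as.list(specs[idx[i], ])
    params <- draw_dive_params(sp, seafloor[i])
    params$duration_min <- dur_min[i]   # keep the timeline from pass 1
    params$pdi_min <- pdi_min[i]
    prof <- generate_dive_profile(sp, seafloor[i], params)
    truth$start_idx[i] <- cursor + 1L
    segs[[2L * i]] <- prof$depth
    cursor <- cursor + length(prof$depth)
    truth$end_idx[i] <- cursor
    truth$max_depth[i] <- max(prof$depth)
    truth$duration_min[i] <- length(prof$depth) / 60
    truth$bottom_fraction[i] <- params$bottom_fraction
    segs[[2L * i + 1L]] <- stats::runif(pdi_s[i], 0, 0.5)
    cursor <- cursor + pdi_s[i]
  }
  segs[[2L * n + 2L]] <- stats::runif(lead_s, 0, 0.5)
  depth <- unlist(segs, use.names = FALSE)
  truth$start_time <- config$start_time + truth$start_idx - 1
  truth$end_time <- config$start_time + truth$end_idx - 1

  series <- depth_series(depth, config$start_time, config$tag_id, config$utc_offset)

  # Fastloc attempts after Qualifying Dives.
  set.seed(config$seed + 3L)
  qual <- truth$duration_min > 10 & truth$max_depth > 10
  fix_t <- numeric(0)
  for (i in which(qual)) {
    t1 <- truth$end_idx[i] + 2
    if (stats::runif(1) < config$fix_success_prob) fix_t <- c(fix_t, t1)
    if (pdi_s[i] > 300 + 2) {  # still at surface five minutes later
      if (stats::runif(1) < config$fix_success_prob) fix_t <- c(fix_t, t1 + 300)
    }
  }
  if (length(fix_t) == 0) {
    fixes <- data.frame(tag_id = character(), time = as.POSIXct(character(), tz = "UTC"),
                        lon = numeric(), lat = numeric())
  } else {
    fix_times <- config$start_time + fix_t - 1
    fpos <- track_position(track, fix_times)
    fixes <- data.frame(tag_id = config$tag_id, time = fix_times,
                        lon = fpos$lon, lat = fpos$lat)
    fixes <- fixes[order(fixes$time), , drop = FALSE]
  }

  structure(list(series = series, fixes = fixes, bathy = bathy,
                 truth = truth, track = track, config = config),
            class = "adb_deployment")
}

#' @export
print.adb_deployment <- function(x, ...) {
  cat(sprintf("<adb_deployment> %d dives, %d fixes, %.1f days of 1-Hz depth\n",
              nrow(x$truth), nrow(x$fixes), length(x$series$depth) / 86400))
  invisible(x)
}

#' Simulate Argos-style Behavior Messages
#'
#' Only Qualifying Dives (> 10 min duration and > 10 m depth) are summarised,
#' grouped four per message in time order; residual dives not filling a
#' message are dropped. Each slot reports start time, maximum depth, dive
#' duration, a shape code and the post-dive interval. The transmitted shape
#' code is derived from the bottom fraction (V < 0.2, Square >= 0.5, else U);
#' this rule is an invented stand-in for unspecified tag firmware.
#'
#' @param dives Data frame with `start_time`, `max_depth`, `duration_min`,
#'   `bottom_fraction` and `pdi_min` (e.g. the `truth` table of a
#'   deployment).
#' @return A data frame with `message`, `slot` (1-4) and the five reported
#'   fields.
#' @export
simulate_behavior_messages <- function(dives) {
  d <- dives[order(dives$start_time), , drop = FALSE]
  q <- d[d$duration_min > 10 & d$max_depth > 10, , drop = FALSE]
  n_msg <- nrow(q) %/% 4L
  if (n_msg == 0) {
    return(data.frame(message = integer(), slot = integer(),
                      start_time = as.POSIXct(character(), tz = "UTC"),
                      max_depth = numeric(), duration_min = numeric(),
                      shape = character(), pdi_min = numeric()))
  }
  q <- q[seq_len(4L * n_msg), , drop = FALSE]
  shape <- ifelse(q$bottom_fraction < 0.2, "V",
                  ifelse(q$bottom_fraction >= 0.5, "Square", "U"))
  data.frame(message = rep(seq_len(n_msg), each = 4L), slot = rep(1:4, n_msg),
             start_time = q$start_time, max_depth = q$max_depth,
             duration_min = q$duration_min, shape = shape, pdi_min = q$pdi_min)
}
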