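#' Assign locations to dives from a GPS fix table
#'
#' A dive occurring within 2 min of a fix takes that fix's coordinates
#' directly (nearest fix in time; an exact tie takes the earlier fix).
#' Remaining dives are located by linear interpolation in lon/lat between
#' the temporally closest fixes before and after the dive, weighted by the
#' dive time's fractional position between the two fix times. Dives more
#' than 60 min from the temporally closest fix, or with no bracketing pair,
#' are marked spatially invalid and excluded from location-dependent
#' analyses. The dive's start time anchors all time comparisons.
#'
#' @param dives Dive table from [detect_dives()].
#' @param fixes Data frame `time` (POSIXct UTC), `lon`, `lat`, time-ordered.
#' @param direct_window_min Direct-assignment window (min), default 2.
#' @param max_gap_min Validity cutoff (min) to the nearest fix, default 60.
#' @return `dives` with columns `lon`, `lat`, `location_kind`
#'   ("direct"/"interpolated"/"none"), `gap_to_nearest_fix` (min) and
#'   `spatial_valid` appended.
#' @export
assign_locations <- function(dives, fixes, direct_window_min = 2,
                             max_gap_min = 60) {
  n <- nrow(dives)
  out <- dives
  out$lon <- NA_real_; out$lat <- NA_real_
  out$location_kind <- "none"
  out$gap_to_nearest_fix <- NA_real_
  out$spatial_valid <- FALSE
  if (is.null(fixes) || nrow(fixes) == 0 || n == 0) return(out)
  ft <- as.numeric(fixes$time)
  if (is.unsorted(ft)) stop("fixes must be time-ordered")
  dt <- as.numeric(dives$start_time)
  for (i in seq_len(n)) {
    gaps <- abs(ft - dt[i])
    j <- which.min(gaps)  # ties -> earlier fix
    gap_min <- gaps[j] / 60
    out$gap_to_nearest_fix[i] <- gap_min
    if (gap_min <= direct_window_min) {
      out$lon[i] <- fixes$lon[j]; out$lat[i] <- fixes$lat[j]
      out$location_kind[i] <- "direct"
      out$spatial_valid[i] <- gap_min <= max_gap_min
      next
    }
    before <- which(ft <= dt[i])
    after <- which(ft >= dt[i])
    if (length(before) == 0 || length(after) == 0) next  # no bracketing pair
    b <- max(before); a <- min(after)
    w <- (dt[i] - ft[b]) / (ft[a] - ft[b])
    out$lon[i] <- fixes$lon[b] + w * (fixes$lon[a] - fixes$lon[b])
    out$lat[i] <- fixes$lat[b] + w * (fixes$lat[a] - fixes$lat[b])
    out$location_kind[i] <- "interpolated"
    out$spatial_valid[i] <- gap_min <= max_gap_min
  }
  out
}

#' Speed of linear travel between two located dives
#'
#' Great-circle (haversine, R = 6371 km) distance between the dive locations
#' divided by the elapsed time between dive start times: a minimum
#' conservative swim speed.
#'
#' @param lon1,lat1,time1 Previous dive location and start time.
#' @param lon2,lat2,time2 Current dive location and start time.
#' @return Speed in km/hr (vectorised); NA where elapsed time is zero.
#' @export
compute_speed <- function(lon1, lat1, time1, lon2, lat2, time2) {
  dt_hr <- as.numeric(difftime(time2, time1, units = "hours"))
  d_km <- gc_dist_km(lon1, lat1, lon2, lat2)
  ifelse(dt_hr > 0, d_km / dt_hr, NA_real_)
}

#' Turning angle at the middle of three sequential dive locations
#'
#' The absolute difference between the heading from the first to the second
#' location and the heading from the second to the third, wrapped into
#' [0, 180] degrees.
#'
#' @param lon1,lat1,lon2,lat2,lon3,lat3 Three time-ordered locations.
#' @return Angle in degrees (vectorised); NA where consecutive points
#'   coincide (heading undefined).
#' @export
compute_turning_angle <- function(lon1, lat1, lon2, lat2, lon3, lat3) {
  b1 <- gc_bearing(lon1, lat1, lon2, lat2)
  b2 <- gc_bearing(lon2, lat2, lon3, lat3)
  same12 <- lon1 == lon2 & lat1 == lat2
  same23 <- lon2 == lon3 & lat2 == lat3
  out <- wrap_angle_180(b1 - b2)
  out[same12 | same23] <- NA_real_
  out
}

#' Distance from the bottom of a dive to the seafloor
#'
#' Looks up seafloor depth at the dive location (nearest grid cell). Whales
#' are sometimes recorded diving deeper than the charted depth (location
#' uncertainty, steep bathymetry, chart error); in that case the dive's
#' maximum depth is assumed to be the seafloor depth, so the returned
#' distance is never negative.
#'
#' @param max_depth Dive maximum depth(s), m.
#' @param lon,lat Dive location(s).
#' @param grid A `bathy_grid`.
#' @return Distance to seafloor (m, >= 0); NA outside the grid extent.
#' @export
distance_to_seafloor <- function(max_depth, lon, lat, grid) {
  seafloor <- bathy_lookup(grid, lon, lat)
  seafloor <- pmax(seafloor, max_depth)
  seafloor - max_depth
}
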