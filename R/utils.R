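# Internal helpers shared across modules.

# Earth radius used for all spherical distance work (km).
EARTH_RADIUS_KM <- 6371

#' Great-circle distance between points (haversine, R = 6371 km)
#'
#' @param lon1,lat1,lon2,lat2 Coordinates in decimal degrees (WGS-84).
#' @return Distance in kilometres (vectorised).
#' @keywords internal
gc_dist_km <- function(lon1, lat1, lon2, lat2) {
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                           r = EARTH_RADIUS_KM * 1000) / 1000
}

# Initial bearing a -> b in degrees [0, 360).
gc_bearing <- function(lon1, lat1, lon2, lat2) {
  b <- geosphere::bearing(cbind(lon1, lat1), cbind(lon2, lat2))
  (b + 360) %% 360
}

# Absolute heading difference wrapped into [0, 180].
wrap_angle_180 <- function(a) {
  d <- abs(a) %% 360
  ifelse(d > 180, 360 - d, d)
}

# Log-normal draws parameterised by the *median* and a multiplicative
# dispersion factor (> 1); optional truncation by rejection.
rlnorm_med <- function(n, median, dispersion, lower = 0, upper = Inf) {
  stopifnot(median > 0, dispersion >= 1)
  sdlog <- log(dispersion)
  out <- stats::rlnorm(n, meanlog = log(median), sdlog = sdlog)
  bad <- which(out < lower | out > upper)
  guard <- 0L
  while (length(bad) > 0 && guard < 1000L) {
    out[bad] <- stats::rlnorm(length(bad), meanlog = log(median), sdlog = sdlog)
    bad <- bad[out[bad] < lower | out[bad] > upper]
    guard <- guard + 1L
  }
  if (length(bad) > 0) out[bad] <- pmin(pmax(out[bad], lower), upper)
  out
}

# Stationary AR(1) series with given marginal sd (mean 0).
ar1_noise <- function(n, sd, rho = 0.95) {
  if (n <= 0) return(numeric(0))
  if (sd <= 0) return(rep(0, n))
  innov_sd <- sd * sqrt(1 - rho^2)
  x <- numeric(n)
  x[1] <- stats::rnorm(1, 0, sd)
  if (n > 1) for (i in 2:n) x[i] <- rho * x[i - 1] + stats::rnorm(1, 0, innov_sd)
  x
}

clamp <- function(x, lo = -Inf, hi = Inf) pmin(pmax(x, lo), hi)

`%||%` <- function(a, b) if (is.null(a)) b else a
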