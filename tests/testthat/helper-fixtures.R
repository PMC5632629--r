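# Shared fixtures, built once per test run.

# Small deployment for unit tests (300 dives).
small_deployment <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_deployment(scenario_config(n_dives_per_type = 50, seed = 42))
    }
    cache
  }
})

# Full-size deployment for the recovery checks (1,200 dives, balanced).
big_deployment <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_deployment(scenario_config(n_dives_per_type = 200, seed = 1))
    }
    cache
  }
})

big_analysis <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      dep <- big_deployment()
      cache <<- run_dive_pipeline(dep$series, dep$fixes, dep$bathy)
    }
    cache
  }
})

# A trapezoidal dive embedded in a surface record: linear 1 m/s descent to
# `depth`, flat bottom, 1 m/s ascent; returns the series and the truth.
make_trapezoid_series <- function(depth = 400, bottom_s = 600, pad_s = 120) {
  d <- c(rep(0, pad_s), seq(1, depth), rep(depth, bottom_s - 1),
         seq(depth - 1, 1), rep(0, pad_s))
  depth_series(d, as.POSIXct("2008-06-01", tz = "UTC"), "trap")
}

# Pure V dive: strict descent then strict ascent, no flat samples.
make_v_series <- function(depth = 200, pad_s = 60) {
  d <- c(rep(0, pad_s), seq(1, depth), seq(depth - 1, 1), rep(0, pad_s))
  depth_series(d, as.POSIXct("2008-06-01", tz = "UTC"), "vdive")
}

# Two-step descent: pause (flat) at `pause_depth`, then continue to a flat
# bottom at `bottom_depth`; mirrored two-step ascent optional.
make_shoulder_dive <- function(pause_depth = 100, bottom_depth = 450,
                               pause_s = 30, bottom_s = 300) {
  c(seq(1, pause_depth), rep(pause_depth, pause_s),
    seq(pause_depth + 1, bottom_depth), rep(bottom_depth, bottom_s),
    seq(bottom_depth - 1, 1))
}

# Random reflecting-walk depth series that wanders across the surface,
# producing assorted submergence runs for detector cross-checks.
random_depth_series <- function(n = 3600, drift_sd = 0.8) {
  d <- pmax(0, cumsum(stats::rnorm(n, 0, drift_sd)))
  depth_series(d, as.POSIXct("2008-06-01", tz = "UTC"), "rand")
}
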