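test_that("dive detection handles degenerate and constructed cases", {
  cfg <- detection_config()
  flat <- depth_series(rep(0, 600))
  expect_identical(nrow(detect_dives(flat, cfg)), 0L)

  sq <- depth_series(c(rep(0, 30), rep(100, 300), rep(0, 30)))
  dv <- detect_dives(sq, cfg)
  expect_identical(nrow(dv), 1L)
  expect_equal(dv$max_depth, 100)
  expect_equal(dv$duration_min, 5)

  # fails duration (50 s) despite sufficient depth
  short <- depth_series(c(rep(0, 30), rep(12, 50), rep(0, 30)))
  expect_identical(nrow(detect_dives(short, cfg)), 0L)
  # fails depth (8 m) despite sufficient duration
  shallow <- depth_series(c(rep(0, 30), rep(8, 600), rep(0, 30)))
  expect_identical(nrow(detect_dives(shallow, cfg)), 0L)

  one <- depth_series(50)
  expect_identical(nrow(detect_dives(one, cfg)), 0L)
})

test_that("detector equals the exhaustive brute-force scan on random series", {
  cfg <- detection_config()
  set.seed(101)
  for (rep in 1:25) {
    s <- random_depth_series(3600)
    got <- detect_dives(s, cfg)
    want <- brute_detect_dives(s$depth)
    expect_identical(nrow(got), nrow(want))
    if (nrow(want) > 0) {
      expect_identical(got$start_idx, as.integer(want$start))
      expect_identical(got$end_idx, as.integer(want$end))
      expect_equal(got$max_depth, want$max_depth)
    }
  }
})

test_that("raising detection thresholds never increases the dive count", {
  set.seed(202)
  for (rep in 1:10) {
    s <- random_depth_series(3600)
    base <- nrow(detect_dives(s, detection_config()))
    expect_lte(nrow(detect_dives(s, detection_config(min_depth = 20))), base)
    expect_lte(nrow(detect_dives(s, detection_config(min_duration = 120))), base)
  }
})

test_that("phase segmentation: pure V collapses the bottom to the apex", {
  d <- c(seq(1, 200), seq(199, 1))
  ph <- segment_phases(d)
  expect_identical(ph$descent_end, 200L)
  expect_identical(ph$ascent_start, 200L)
})

test_that("phase segmentation: trapezoid boundaries at the flat edges; partition exact", {
  d <- c(seq(1, 400), rep(400, 599), seq(399, 1))  # flat spans samples 400..999
  ph <- segment_phases(d)
  expect_identical(ph$descent_end, 400L)
  expect_identical(ph$ascent_start, 999L)
  n <- length(d)
  descent <- ph$descent_end - 1L
  bottom <- ph$ascent_start - ph$descent_end + 1L
  ascent <- n - ph$ascent_start
  expect_identical(descent + bottom + ascent, n)
})

test_that("noisy square dives: descent end lands near the true bottom start", {
  set.seed(33)
  for (rep in 1:100) {
    wiggle <- cumsum(rnorm(600, 0, 0.8)); wiggle <- wiggle - mean(wiggle)
    d <- c(seq(1, 300), 300 + pmin(pmax(wiggle, -2), 2), seq(299, 1))
    ph <- segment_phases(d)
    expect_lte(abs(ph$descent_end - 300L), 15L)
  }
})

test_that("shoulder rule: hand-computed ratio cases", {
  cfg <- detection_config()
  deep_pause <- make_shoulder_dive(pause_depth = 100, bottom_depth = 450)
  ph <- segment_phases(deep_pause, cfg)
  expect_equal(deep_pause[ph$descent_end], 100)   # pause mistaken for bottom
  ref <- refine_shoulders(deep_pause, ph, cfg)    # 100/450 = 0.222 < 0.68
  expect_equal(deep_pause[ref$descent_end], 450)
  expect_equal(ref$descent_shoulder_depth, 100)

  mild_pause <- make_shoulder_dive(pause_depth = 350, bottom_depth = 450)
  ph2 <- segment_phases(mild_pause, cfg)
  ref2 <- refine_shoulders(mild_pause, ph2, cfg)  # 350/450 = 0.778 >= 0.68
  expect_identical(ref2$descent_end, ph2$descent_end)
  expect_true(is.na(ref2$descent_shoulder_idx))

  v <- c(seq(1, 300), seq(299, 1))
  phv <- segment_phases(v, cfg)
  refv <- refine_shoulders(v, phv, cfg)
  expect_identical(refv$descent_end, phv$descent_end)
  expect_true(is.na(refv$descent_shoulder_idx))

  # idempotence: a second application changes nothing
  again <- refine_shoulders(deep_pause, ref, cfg)
  expect_identical(again$descent_end, ref$descent_end)
  expect_identical(again$ascent_start, ref$ascent_start)
})

test_that("shoulder rule works symmetrically on the ascent side", {
  cfg <- detection_config()
  d <- c(seq(1, 450), rep(450, 300), seq(449, 101), rep(100, 30), seq(99, 1))
  ph <- segment_phases(d, cfg)
  expect_equal(d[ph$ascent_start], 100)           # ascent pause mistaken for bottom end
  ref <- refine_shoulders(d, ph, cfg)
  expect_equal(d[ref$ascent_start], 450)
  expect_equal(ref$ascent_shoulder_depth, 100)
})

test_that("segmentation invariants hold across a synthetic deployment", {
  dep <- small_deployment()
  dv <- detect_dives(dep$series)
  cfg <- detection_config()
  for (i in seq_len(nrow(dv))) {
    d <- dep$series$depth[dv$start_idx[i]:dv$end_idx[i]]
    ph0 <- segment_phases(d, cfg)
    ph <- refine_shoulders(d, ph0, cfg)
    n <- length(d)
    expect_true(ph$descent_end >= 1 && ph$descent_end <= ph$ascent_start &&
                  ph$ascent_start <= n)
    # refinement only ever tightens the bottom phase
    expect_gte(ph$descent_end, ph0$descent_end)
    expect_lte(ph$ascent_start, ph0$ascent_start)
    expect_identical((ph$descent_end - 1L) +
                       (ph$ascent_start - ph$descent_end + 1L) +
                       (n - ph$ascent_start), n)
  }
})

test_that("depth CSV round-trips through write/read and splits on gaps", {
  dep <- generate_deployment(scenario_config(n_dives_per_type = 2, seed = 5))
  dir <- tempfile(); paths <- write_deployment_csv(dep, dir)
  back <- read_depth_csv(paths["depth"])
  expect_identical(length(back), 1L)
  expect_equal(back[[1]]$depth, round(dep$series$depth, 2))
  expect_identical(back[[1]]$start_time, dep$series$start_time)
  fx <- read_fix_csv(paths["fixes"])
  expect_identical(nrow(fx), nrow(dep$fixes))
  expect_equal(fx$lon, dep$fixes$lon)

  # a gap splits the record
  df <- utils::read.csv(paths["depth"])
  df <- df[-(100:110), ]
  p2 <- file.path(dir, "gap.csv"); utils::write.csv(df, p2, row.names = FALSE)
  expect_identical(length(read_depth_csv(p2)), 2L)
  unlink(dir, recursive = TRUE)
})
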