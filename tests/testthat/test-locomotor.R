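# locomotor: distance binning, interval AUCs, dark response, lights-on windows

test_that("distance_series bins Euclidean steps by midpoint", {
  # stationary fish: all bins zero
  still <- trajectory(seq(0, 60, 0.1), rep(3, 601), rep(4, 601))
  expect_true(all(distance_series(still, 10)$distance_mm == 0))

  # constant speed v along a line: every bin v * bin_width
  v <- 2.5
  ser <- distance_series(straight_trajectory(v = v, T = 60, fr = 10), 10)
  expect_equal(nrow(ser), 6)
  expect_equal(ser$distance_mm, rep(v * 10, 6), tolerance = 1e-9)

  # square path 4 x 10 mm traversed once inside one bin: 40 mm
  tsq <- seq(0, 8, by = 1)
  xsq <- c(0, 5, 10, 10, 10, 5, 0, 0, 0)
  ysq <- c(0, 0, 0, 5, 10, 10, 10, 5, 0)
  sq <- trajectory(tsq, xsq, ysq, frame_rate = 1)
  ssq <- distance_series(sq, 10)
  expect_equal(nrow(ssq), 1)
  expect_equal(ssq$distance_mm, 40)

  expect_error(distance_series(trajectory(1:5, rep(NA_real_, 5), rep(NA_real_, 5))),
               "fewer than 2 tracked frames")
})

test_that("total distance is conserved across binning", {
  set.seed(11)
  t <- seq(0, 120, by = 1 / 30)
  x <- cumsum(rnorm(length(t), 0, 0.3)); y <- cumsum(rnorm(length(t), 0, 0.3))
  tr <- trajectory(t, x, y, frame_rate = 30)
  raw <- sum(sqrt(diff(x)^2 + diff(y)^2))
  for (bw in c(5, 10, 60))
    expect_equal(sum(distance_series(tr, bw)$distance_mm), raw,
                 tolerance = 1e-9)
})

test_that("long tracking gaps flag bins and contribute no distance", {
  t <- seq(0, 60, 0.5)
  x <- 2 * t; y <- rep(0, length(t))
  x[t > 20 & t < 25] <- NA              # 4.5-s dropout inside bin 3
  tr <- trajectory(t, x, y, frame_rate = 2)
  ser <- distance_series(tr, 10, gap_tolerance_s = 1)
  expect_true(any(ser$flagged))
  expect_true(all(which(ser$flagged) %in% c(3)))
  # distance in the flagged bin excludes the bridged gap step
  expect_lt(ser$distance_mm[3], 20)
  # short gaps (below tolerance) are bridged by the straight-line step
  x2 <- 2 * t; x2[t == 30.5] <- NA
  ser2 <- distance_series(trajectory(t, x2, y, frame_rate = 2), 10)
  expect_false(any(ser2$flagged))
  expect_equal(sum(ser2$distance_mm), 120, tolerance = 1e-9)
})

test_that("interval_auc sums bins, is additive, and rejects misalignment", {
  ser <- make_series(rep(5, 360), bin_width_s = 10)     # 1 h at 5 mm / 10 s
  m <- interval_auc(ser, start_s = 0, end_s = 1800)
  expect_equal(m$auc_mm, 900)                           # 180 bins x 5 mm
  expect_equal(m$n_bins, 180)

  a <- interval_auc(ser, start_s = 0, end_s = 600)$auc_mm
  b <- interval_auc(ser, start_s = 600, end_s = 1800)$auc_mm
  expect_equal(a + b, 900)

  expect_error(interval_auc(ser, start_s = 5, end_s = 1805), "not aligned")
  expect_error(interval_auc(ser, start_s = 0, end_s = 7200), "exceeds")

  # flagged bins contribute 0 but are reported
  ser2 <- make_series(c(5, 0, 5), flagged = c(FALSE, TRUE, FALSE))
  m2 <- interval_auc(ser2, start_s = 0, end_s = 30)
  expect_equal(m2$n_flagged, 1)
})

test_that("condition_aggregate pools same-condition intervals", {
  sched <- photokinesis_schedule()
  # 185 min of bins: 5 mm per 10-s bin in light, 2 mm in dark
  per_bin <- vapply(seq(0, 185 * 60 - 10, by = 10), function(t0) {
    iv <- condition_at(sched, t0)
    if (iv$condition == "white") 5 else 2
  }, numeric(1))
  ser <- make_series(per_bin, bin_width_s = 10)
  agg <- condition_aggregate(ser, sched)
  expect_equal(agg$auc_mm[agg$condition == "white"], 3 * 180 * 5)  # 2700
  expect_equal(agg$auc_mm[agg$condition == "dark"], 3 * 180 * 2)
  # acclimation excluded by default, included on request
  agg2 <- condition_aggregate(ser, sched, include_acclimation = TRUE)
  expect_equal(agg2$auc_mm[agg2$condition == "dark"], 3 * 180 * 2 + 30 * 2)
  # series shorter than the schedule: missing interval is an error
  expect_error(condition_aggregate(make_series(rep(1, 10)), sched), "exceeds")
})

test_that("normalized_dark_response divides response by preceding-dark baseline", {
  sched <- photokinesis_schedule()
  # acclimation darkness at 5 mm/bin, light at 8, post-light darkness at 10
  per_bin <- vapply(seq(0, 185 * 60 - 10, by = 10), function(t0) {
    iv <- condition_at(sched, t0)
    if (iv$acclimation) 5 else if (iv$condition == "white") 8 else 10
  }, numeric(1))
  ser <- make_series(per_bin, bin_width_s = 10)
  dr <- normalized_dark_response(ser, sched)
  expect_equal(dr$ratio, 2)                    # 10 / 5
  expect_equal(dr$transition_s, 2100)
  expect_true(is.na(dr$flag))

  # scale invariance: recalibrating all distances by c leaves the ratio alone
  dr2 <- normalized_dark_response(make_series(3.7 * per_bin, 10), sched)
  expect_equal(dr2$ratio, dr$ratio, tolerance = 1e-12)

  # zero baseline flags an undefined result instead of erroring
  zero <- ifelse(seq_along(per_bin) <= 30, 0, per_bin)
  dr3 <- normalized_dark_response(make_series(zero, 10), sched)
  expect_true(is.na(dr3$ratio))
  expect_identical(dr3$flag, "zero_baseline")

  # no preceding darkness -> error
  no_dark <- build_schedule(data.frame(condition = c("white", "dark"),
                                       duration_s = c(1800, 1800)))
  expect_error(normalized_dark_response(make_series(rep(1, 360), 10), no_dark),
               "no darkness precedes")
})

test_that("lights_on_windows nests 30-min inside 90-min per transition", {
  sched <- diel_schedule(days = 2)
  a <- 3                                        # mm per 1-min bin
  ser <- make_series(rep(a, 48 * 60), bin_width_s = 60)
  won <- lights_on_windows(ser, sched)
  expect_equal(nrow(won), 4)                    # 2 transitions x 2 windows
  expect_equal(won$auc_mm[won$window_s == 1800], rep(30 * a, 2))
  expect_equal(won$auc_mm[won$window_s == 5400], rep(90 * a, 2))
  expect_equal(unique(won$t_on_s), c(8, 32) * 3600)

  set.seed(13)
  ser2 <- make_series(runif(48 * 60, 0, 6), bin_width_s = 60)
  won2 <- lights_on_windows(ser2, sched)
  for (k in unique(won2$transition)) {
    d <- won2[won2$transition == k, ]
    expect_lte(d$auc_mm[d$window_s == 1800], d$auc_mm[d$window_s == 5400])
  }
  expect_error(lights_on_windows(ser, sched, windows_s = 17 * 3600),
               "exceeds")
})

test_that("trajectory CSVs round-trip, including missing frames", {
  dir <- withr::local_tempdir()
  tr1 <- straight_trajectory(v = 1, T = 5, fr = 4, subject_id = "f1")
  tr2 <- straight_trajectory(v = 2, T = 5, fr = 4, subject_id = "f2",
                             genotype = "mutant")
  tr2$x_mm[3] <- NA; tr2$y_mm[3] <- NA
  path <- write_trajectories(list(tr1, tr2), file.path(dir, "traj.csv"))
  back <- read_trajectories(path, frame_rate = 4)
  expect_setequal(names(back), c("f1", "f2"))
  expect_equal(back$f2$x_mm, tr2$x_mm)
  expect_equal(back$f2$genotype, "mutant")
  expect_error(read_trajectories({
    p <- file.path(dir, "empty.csv")
    write.csv(data.frame(subject_id = character(), t_s = numeric(),
                         x_mm = numeric(), y_mm = numeric()), p,
              row.names = FALSE)
    p
  }), "empty trajectory")
})
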