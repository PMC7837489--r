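# lightfield: spectra, photon flux, contrast, schedules

test_that("photon_flux integrates tabulated spectra correctly", {
  # zero irradiance integrates to zero
  expect_equal(photon_flux(spectrum(380:700, rep(0, 321))), 0)

  # narrow rectangular band at 500 nm carrying 3.9729e-7 W m^-2 total power:
  # oracle N = P * lambda / (h c) = 1e12 photons m^-2 s^-1
  band <- spectrum(c(499, 500, 501), rep(3.9729e-7 / 2, 3))
  expect_equal(photon_flux(band), 1e12, tolerance = 1e-4)

  # linear in irradiance, additive over spectra on a shared grid
  set.seed(1)
  grid <- seq(400, 700, by = 5)
  e1 <- runif(length(grid)); e2 <- runif(length(grid))
  s1 <- spectrum(grid, e1); s2 <- spectrum(grid, e2)
  for (ab in list(c(2, 0), c(0.5, 3), c(1, 1))) {
    mix <- spectrum(grid, ab[1] * e1 + ab[2] * e2)
    expect_equal(photon_flux(mix),
                 ab[1] * photon_flux(s1) + ab[2] * photon_flux(s2))
  }
})

test_that("single-sample spectra need an explicit bandwidth", {
  mono <- spectrum(500, 3.9729e-7)
  expect_error(photon_flux(mono), "cannot integrate")
  expect_equal(photon_flux(mono, bandwidth_nm = 1), 1e12, tolerance = 1e-4)
})

test_that("spectrum validation rejects malformed input", {
  expect_error(spectrum(c(500, 500), c(1, 1)), "strictly increasing")
  expect_error(spectrum(c(500, 400), c(1, 1)), "strictly increasing")
  expect_error(spectrum(500, -1), ">= 0")
  expect_error(spectrum(numeric(0), numeric(0)), "at least one sample")
})

test_that("scale_intensity reproduces the 35%-intensity flux", {
  expect_equal(scale_intensity(2.2e13, 0.35), 0.77e13, tolerance = 1e-12)
  expect_identical(scale_intensity(3.1e12, 1), 3.1e12)
  expect_identical(scale_intensity(3.1e12, 0), 0)
  expect_error(scale_intensity(1e12, 1.2), "\\[0, 1\\]")
  expect_error(scale_intensity(1e12, -0.1), "\\[0, 1\\]")
})

test_that("michelson_contrast follows the luminance formula", {
  expect_equal(michelson_contrast(1, 0), 1)
  expect_equal(michelson_contrast(0.42, 0.42), 0)
  # dot vs background luminances at the 35%-intensity screen setting
  expect_equal(michelson_contrast(0.35, 0.0127), 0.930, tolerance = 5e-4)
  # scale invariance, exactly
  set.seed(2)
  for (i in 1:20) {
    lmin <- runif(1); lmax <- lmin + runif(1); c0 <- runif(1, 0.01, 100)
    expect_equal(michelson_contrast(lmax * c0, lmin * c0),
                 michelson_contrast(lmax, lmin), tolerance = 1e-12)
    expect_gte(michelson_contrast(lmax, lmin), 0)
    expect_lte(michelson_contrast(lmax, lmin), 1)
  }
  expect_error(michelson_contrast(0, 0), "undefined contrast")
  expect_error(michelson_contrast(1, 2), "l_max >= l_min")
})

test_that("build_schedule conserves durations and flags acclimation", {
  blocks <- data.frame(condition = c("white", "dark"),
                       duration_s = c(1800, 1800))
  bare <- build_schedule(blocks, repeats = 3)
  expect_equal(schedule_duration(bare), 3 * 3600)

  sched <- build_schedule(blocks, repeats = 3, acclimation_s = 300)
  expect_equal(schedule_duration(sched), 185 * 60)
  expect_equal(schedule_duration(sched, include_acclimation = FALSE), 180 * 60)
  expect_length(analysis_intervals(sched), 6)
  expect_true(sched$intervals[[1]]$acclimation)

  # sum of interval lengths equals the declared total (conservation)
  lens <- vapply(sched$intervals, function(iv) iv$end_s - iv$start_s,
                 numeric(1))
  expect_equal(sum(lens), schedule_duration(sched))

  diel <- diel_schedule(days = 2)
  expect_length(diel$intervals, 4)
  expect_equal(schedule_duration(diel), 48 * 3600)
  expect_equal(diel$origin_zt, 16)

  expect_error(build_schedule(data.frame(condition = "dark", duration_s = 0)),
               "> 0")
})

test_that("half-open intervals give every time point one owner", {
  sched <- photokinesis_schedule()
  expect_identical(condition_at(sched, 0)$condition, "dark")      # acclimation
  expect_identical(condition_at(sched, 300)$condition, "white")   # boundary
  expect_identical(condition_at(sched, 2099.999)$condition, "white")
  expect_identical(condition_at(sched, 2100)$condition, "dark")
  expect_null(condition_at(sched, schedule_duration(sched)))
})

test_that("overlapping or non-contiguous intervals are rejected", {
  a <- light_interval(0, 10, "dark")
  b <- light_interval(5, 20, "white")
  c <- light_interval(12, 20, "white")
  expect_error(light_schedule(list(a, b)), "contiguous")
  expect_error(light_schedule(list(a, c)), "contiguous")
  expect_error(light_interval(10, 10, "dark"), "end > start")
})

test_that("spectrum and schedule files round-trip", {
  dir <- withr::local_tempdir()
  s <- spectrum(seq(400, 700, 10), runif(31), label = "screen")
  p <- write_spectrum(s, file.path(dir, "spec.csv"))
  s2 <- read_spectrum(p, label = "screen")
  expect_equal(s2$wavelength_nm, s$wavelength_nm)
  expect_equal(s2$irradiance, s$irradiance)

  sched <- photokinesis_schedule(light_condition = "blue")
  p2 <- write_schedule(sched, file.path(dir, "sched.json"))
  sched2 <- read_schedule(p2)
  expect_equal(sched2, sched)
})
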