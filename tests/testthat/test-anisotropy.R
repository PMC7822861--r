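test_that("grating factor is the H-channel intensity ratio", {
  expect_equal(grating_factor(polarized_intensities(1, 1, 2, 2)), 1)
  expect_equal(grating_factor(polarized_intensities(1, 1, 0.9, 1.0)), 0.9)
  expect_equal(grating_factor(polarized_intensities(1, 1, 2, 4)), 0.5)
  expect_error(grating_factor(polarized_intensities(1, 1, 2, 0)),
               "invalid calibration")
  expect_error(polarized_intensities(1, -1, 1, 1), "non-negative")
})

test_that("anisotropy formula reproduces the standard limits", {
  expect_equal(anisotropy_from_intensities(polarized_intensities(2, 2), 1), 0)
  expect_equal(anisotropy_from_intensities(polarized_intensities(5, 0), 0.7), 1)
  expect_equal(anisotropy_from_intensities(polarized_intensities(2, 1), 1),
               0.25)
  expect_error(anisotropy_from_intensities(polarized_intensities(0, 0), 1),
               "invalid measurement")

  # bounded in (-0.5, 1] for any non-negative intensities
  set.seed(7)
  for (i in 1:200) {
    I <- polarized_intensities(runif(1, 0.01, 10), runif(1, 0, 10))
    r <- anisotropy_from_intensities(I, runif(1, 0.5, 2))
    expect_gt(r, -0.5)
    expect_lte(r, 1)
  }
})

test_that("the linear binding scale reads 49% occupancy from the Cy5 example", {
  cal <- cy5_calibration()
  f <- bound_fraction(0.268, cal)
  expect_equal(f, (0.268 - 0.242) / (0.295 - 0.242))
  expect_equal(round(100 * f), 49)
  expect_equal(bound_fraction(cal$r_min, cal), 0)
  expect_equal(bound_fraction(cal$r_max, cal), 1)
  # inverse direction
  expect_equal(r_from_bound_fraction(f, cal), 0.268)
  expect_equal(r_from_bound_fraction(0, cal), 0.242)
  expect_equal(r_from_bound_fraction(1, cal), 0.295)
})

test_that("calibration round trip is the identity and out-of-range clips", {
  cal <- anisotropy_calibration(0.05, 0.22, method = "synthetic")
  r <- seq(cal$r_min, cal$r_max, length.out = 101)
  expect_equal(r_from_bound_fraction(bound_fraction(r, cal), cal), r,
               tolerance = 1e-12)

  expect_warning(f <- bound_fraction(c(0.04, 0.1, 0.25), cal), "2 .*clipped")
  expect_equal(f[c(1, 3)], c(0, 1))

  expect_error(anisotropy_calibration(0.3, 0.2), "r_min < r_max")
  expect_error(anisotropy_calibration(0.1, 0.5), "r_max <= 0.4")
  expect_error(r_from_bound_fraction(1.2, cal), "0, 1")
})

test_that("anisotropy traces convert to bound concentrations and back", {
  cal <- atto488_synthetic_calibration()
  ex <- exchange_experiment(A_total = 2, S_total = 0.2, duration = 600)
  sim <- simulate_exchange(ex, ref_rates())
  r <- r_from_bound_fraction(sim$AS / 0.2, cal)
  tc <- new_timecourse(data.frame(time = sim$time, r = r),
                       kind = "anisotropy", experiment = ex)
  conc <- concentrations_from_timecourse(tc, cal)
  expect_equal(timecourse_kind(conc), "bound_concentration")
  expect_equal(conc$bound, sim$AS, tolerance = 1e-12)
  expect_equal(conc$free, 0.2 - sim$AS, tolerance = 1e-12)
  # the constant-intensity assumption is carried in the metadata
  expect_match(attr(conc, "meta")$assumption, "fluorescence")

  # constant r_min trace maps to an all-zero bound series
  flat <- new_timecourse(data.frame(time = sim$time,
                                    r = rep(cal$r_min, nrow(sim))),
                         kind = "anisotropy", experiment = ex)
  expect_true(all(concentrations_from_timecourse(flat, cal)$bound == 0))
  # midpoint r maps to half the label bound
  mid <- new_timecourse(data.frame(time = sim$time,
                                   r = rep((cal$r_min + cal$r_max) / 2,
                                           nrow(sim))),
                        kind = "anisotropy", experiment = ex)
  expect_equal(unique(concentrations_from_timecourse(mid, cal)$bound), 0.1)
})
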