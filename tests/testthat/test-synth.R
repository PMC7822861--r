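test_that("generation is bit-identical under a fixed seed", {
  b1 <- synth_association_bundle(noise_sd = 0.002, seed = 9)
  b2 <- synth_association_bundle(noise_sd = 0.002, seed = 9)
  expect_identical(b1, b2)
  b3 <- synth_association_bundle(noise_sd = 0.002, seed = 10)
  expect_false(identical(b1[[1]]$r, b3[[1]]$r))

  c1 <- synth_chase(noise_sd = 0.002, seed = 9)
  c2 <- synth_chase(noise_sd = 0.002, seed = 9)
  expect_identical(c1, c2)

  t1 <- synth_titration(titration_params(2.1, 0.1, 0.3), 0.5,
                        noise_sd = 0.002, seed = 9)
  t2 <- synth_titration(titration_params(2.1, 0.1, 0.3), 0.5,
                        noise_sd = 0.002, seed = 9)
  expect_identical(t1, t2)

  expect_error(synth_association_bundle(noise_sd = 0.002), "seed")
  expect_error(synth_titration(titration_params(2.1, 0.1, 0.3), 0.5,
                               noise_sd = 0.01), "seed")
})

test_that("noiseless traces invert exactly back to the simulated state", {
  bundle <- synth_association_bundle(noise_sd = 0)
  rt <- ref_rates()
  for (tc in bundle) {
    ex <- attr(tc, "experiment")
    cal <- attr(tc, "meta")$calibration
    conc <- concentrations_from_timecourse(tc, cal)
    sim <- simulate_exchange(ex, rt)
    expect_equal(conc$bound, sim$AS, tolerance = 1e-10)
  }
})

test_that("a zero-analogue trace sits at the calibration floor", {
  bundle <- synth_association_bundle(S_totals = c(0, 0.1), noise_sd = 0)
  cal <- attr(bundle[[1]], "meta")$calibration
  expect_true(all(bundle[[1]]$r == cal$r_min))
  expect_true(all(bundle[[2]]$r[-1] > cal$r_min))  # t = 0 starts at the floor
})

test_that("generated noise has the configured magnitude", {
  noisy <- synth_association_bundle(noise_sd = 0.002, seed = 21)
  clean <- synth_association_bundle(noise_sd = 0)
  res <- unlist(Map(function(a, b) a$r - b$r, noisy, clean))
  expect_lt(abs(sd(res) / 0.002 - 1), 0.15)
})

test_that("the chase trace decays at the label's off-rate", {
  tc <- synth_chase(noise_sd = 0)
  cal <- attr(tc, "meta")$calibration
  post <- tc$time >= 1800 + 600   # skip the fast rebinding transient
  y <- tc$r[post] - cal$r_min
  # log-slope of the terminal decay vs k_off_S: excess ATP suppresses
  # rebinding, so dissociation of the label dominates
  k_obs <- -coef(lm(log(y) ~ tc$time[post]))[[2]]
  expect_equal(k_obs, 1e-3, tolerance = 0.05)
})

test_that("a zero-ATP chase continues at the exchange plateau", {
  tc <- synth_chase(chase_T_add = 0, noise_sd = 0, duration = 3600)
  post <- tc$r[tc$time >= 1800]
  expect_lt(diff(range(post)), 0.001)
})

test_that("synthetic polarized intensities invert the anisotropy formula", {
  I <- synth_polarized_intensities(0.25, total_intensity = 4, G = 1)
  expect_equal(I[["I_VV"]], 2)
  expect_equal(I[["I_VH"]], 1)

  I0 <- synth_polarized_intensities(0, G = 1)
  expect_equal(I0[["I_VV"]], I0[["I_VH"]])

  set.seed(31)
  for (i in 1:50) {
    r <- runif(1, -0.49, 1)
    G <- runif(1, 0.5, 2)
    I <- synth_polarized_intensities(r, total_intensity = runif(1, 1, 10),
                                     G = G)
    expect_equal(anisotropy_from_intensities(I, grating_factor(I)), r,
                 tolerance = 1e-12)
  }
  expect_error(synth_polarized_intensities(-0.6), "r_target")
  expect_error(synth_polarized_intensities(1.2), "r_target")
})
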