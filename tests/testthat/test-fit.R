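test_that("the global fit recovers generating parameters from noiseless data", {
  fit <- exchange_fit(ref_bundle())
  expect_true(fit$converged)
  expect_equal(coef(fit)[["k_on_T"]], 10)   # fixed by default
  expect_lt(rel_err(coef(fit)[["k_on_S"]], 12), 0.01)
  expect_lt(rel_err(coef(fit)[["k_off_T"]], 2.8e-3), 0.01)
  expect_lt(rel_err(coef(fit)[["k_off_S"]], 1e-3), 0.01)
  expect_lt(fit$rss, 1e-12)

  s <- summary(fit)
  expect_equal(s$ratio, 1.2, tolerance = 1e-6)
})

test_that("a fit with no free parameters is the identity on its own data", {
  bundle <- ref_bundle()
  fit <- exchange_fit(bundle, fixed = ref_truth)
  expect_equal(fit$rss, 0, tolerance = 1e-18)
  expect_equal(coef(fit), ref_truth)
  expect_equal(fit$niter, 0L)
})

test_that("estimates are invariant to dataset order", {
  bundle <- ref_bundle()
  f1 <- exchange_fit(bundle)
  f2 <- exchange_fit(rev(bundle))
  expect_equal(coef(f1), coef(f2), tolerance = 1e-10)
})

test_that("structurally unidentifiable requests are flagged", {
  bundle <- ref_bundle()
  expect_warning(
    expect_warning(exchange_fit(bundle[1:2], fixed = numeric(0)),
                   "only their ratio"),
    "chase")
  expect_warning(exchange_fit(bundle[1:4]), "chase")
})

test_that("anisotropy datasets are fitted through their calibration", {
  # drop the stored calibration and supply it explicitly instead
  bundle <- ref_bundle()
  stripped <- lapply(bundle, function(tc) {
    attr(tc, "meta")$calibration <- NULL
    tc
  })
  expect_error(exchange_fit(stripped), "r_MIN")
  fit <- exchange_fit(stripped, calibration = atto488_synthetic_calibration())
  expect_lt(rel_err(coef(fit)[["k_off_T"]], 2.8e-3), 0.01)
})

test_that("the chase pins down the label off-rate", {
  # detectability of a 20% error in k_off_S (other parameters refit),
  # measured as the residual penalty relative to the noise floor each
  # design would have at the default anisotropy noise: with the chase the
  # error stands out above the noise; without it, it is invisible
  full <- ref_bundle()
  assoc <- synth_association_bundle(noise_sd = 0)
  noise_rss <- function(data) {
    sum(vapply(data, function(tc) {
      ex <- attr(tc, "experiment")
      nrow(tc) * (0.002 / 0.17 * ex$S_total)^2
    }, numeric(1)))
  }
  penalty <- function(data) {
    f <- suppressWarnings(
      exchange_fit(data, fixed = c(k_on_T = 10, k_off_S = 1.2e-3)))
    f$rss / noise_rss(data)
  }
  p_full <- penalty(full)
  p_assoc <- penalty(assoc)
  expect_gt(p_full, 1)            # detectable above the noise with the chase
  expect_lt(p_assoc, 0.5)         # lost in the noise without it
  expect_gt(p_full / p_assoc, 3)
})

test_that("noisy fits recover the identifiable parameter combinations", {
  # with k_on_T anchored, the data constrain k_off_S, the Kd ratio and the
  # product k_on_S * k_off_T tightly; the product's factors individually are
  # ridge-degenerate and are exercised by the identifiability profile instead
  err_prod <- err_S <- numeric(5)
  for (i in 1:5) {
    data <- suppressWarnings(ref_bundle(noise_sd = 0.002, seed = 300 + i))
    fit <- suppressWarnings(exchange_fit(data))
    err_prod[i] <- rel_err(coef(fit)[["k_on_S"]] * coef(fit)[["k_off_T"]],
                           12 * 2.8e-3)
    err_S[i] <- rel_err(coef(fit)[["k_off_S"]], 1e-3)
  }
  expect_lt(median(err_prod), 0.03)
  expect_lt(median(err_S), 0.03)
})

test_that("predict and residuals are consistent with the data", {
  bundle <- ref_bundle()
  fit <- exchange_fit(bundle)
  expect_equal(length(residuals(fit)), sum(fit$n_points))
  expect_lt(max(abs(residuals(fit))), 1e-6)
  pred <- predict(fit)
  expect_s3_class(pred, "timecourse")
  expect_equal(timecourse_kind(pred), "state")
})

test_that("the identifiability profile pins the k_on ratio, not the k_on values", {
  prof <- identifiability_profile(ref_bundle())
  expect_s3_class(prof, "identifiability_profile")
  expect_equal(nrow(prof), 3L)
  expect_true(all(prof$converged))
  # ratio of association constants stable at 1.2 across a 25-fold k_on range
  expect_lt(max(abs(prof$k_on_ratio / 1.2 - 1)), 0.05)
  # fit quality indistinguishable across the grid: every optimum's rms
  # residual is far below the data scale
  scale <- 0.2   # uM, largest analogue concentration in the bundle
  expect_lt(max(prof$rms) / scale, 0.01)

  expect_error(identifiability_profile(ref_bundle(), k_on_T_grid = c(1, 2)),
               "at least 3")
  expect_error(identifiability_profile(ref_bundle(),
                                       k_on_T_grid = c(4, 5, 6)),
               "decade")
})

test_that("perturbing the k_on ratio degrades the fit where shifting k_on does not", {
  # refit the off-rates with both association constants pinned: at the true
  # ratio the model matches; at a ratio off by 20% it cannot
  bundle <- ref_bundle()
  fit_true <- exchange_fit(bundle, fixed = c(k_on_T = 10, k_on_S = 12))
  fit_off <- exchange_fit(bundle, fixed = c(k_on_T = 10, k_on_S = 12 * 1.2))
  expect_gt(fit_off$rss, 100 * fit_true$rss)
  # while scaling both k_on together (same ratio) changes almost nothing
  fit_scaled <- exchange_fit(bundle, fixed = c(k_on_T = 50, k_on_S = 60))
  expect_lt(fit_scaled$rss, 0.01 * fit_off$rss)
})
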