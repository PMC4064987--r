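test_that("an exact 5th-order Fourier series is recovered by the smoother", {
  t <- seq(0, 60, length.out = 38)
  om <- 0.09
  y <- 0.2 + 0.05 * cos(om * t) - 0.12 * sin(om * t) +
    0.02 * cos(2 * om * t) + 0.03 * sin(2 * om * t) -
    0.01 * cos(3 * om * t) + 0.005 * sin(4 * om * t) +
    0.002 * cos(5 * om * t)
  curve <- smooth_ct(concentration_series(t, y, "tissue"), "fourier5")
  expect_lt(curve$rss, 1e-16)
  expect_lt(max(abs(eval_curve(curve, t) - y)), 1e-8)
  expect_equal(curve$coefficients$omega, om, tolerance = 1e-8)
})

test_that("interpolating smoothers pass through knots with documented tie-break", {
  t <- c(0, 1, 2, 3, 4)
  y <- c(0, 0.3, 0.1, 0.5, 0.2)
  lin <- smooth_ct(concentration_series(t, y, "tissue"), "linear")
  expect_equal(eval_curve(lin, t), y)
  expect_equal(eval_curve(lin, 0.5), 0.15)
  near <- smooth_ct(concentration_series(t, y, "tissue"), "nearest")
  expect_equal(eval_curve(near, 1.4), 0.3)   # closer to t = 1
  expect_equal(eval_curve(near, 1.5), 0.3)   # exact midpoint -> earlier
  expect_equal(eval_curve(near, 1.6), 0.1)
  expect_error(eval_curve(near, 5), "domain")
})

test_that("fourier5 smoothing requires enough samples", {
  t <- seq(0, 11)
  expect_error(
    smooth_ct(concentration_series(t, sin(t / 3), "tissue"), "fourier5"),
    "13 samples")
})

test_that("splitting resamples each closed segment on an equal grid", {
  t <- seq(0, 60, length.out = 38)
  lin <- smooth_ct(concentration_series(t, 0.1 + 0.002 * t, "tissue"),
                   "linear")
  parts <- split_and_resample(lin, 20, n = 40L)
  expect_equal(parts$stage1$time, seq(0, 20, length.out = 40))
  expect_equal(diff(parts$stage1$time),
               rep(20 / 39, 39), tolerance = 1e-12)
  expect_equal(parts$stage2$time, seq(20, 60, length.out = 40))
  expect_equal(diff(parts$stage2$time),
               rep(40 / 39, 39), tolerance = 1e-12)
  # split point belongs to both stages
  expect_equal(parts$stage1$value[40], parts$stage2$value[1])
  # values come from the curve
  expect_equal(parts$stage1$value, 0.1 + 0.002 * parts$stage1$time,
               tolerance = 1e-12)
  expect_error(split_and_resample(lin, 60, n = 40L), "inside")
  expect_error(split_and_resample(lin, 20, n = 3L), "at least 4")
})

test_that("a constant curve resamples to constant stages", {
  t <- seq(0, 30, length.out = 15)
  cst <- smooth_ct(concentration_series(t, rep(0.25, 15), "tissue"),
                   "linear")
  parts <- split_and_resample(cst, 10)
  expect_equal(unique(parts$stage1$value), 0.25)
  expect_equal(unique(parts$stage2$value), 0.25)
})

test_that("resampled output refit by the same smoother reproduces the curve", {
  t <- seq(0, 60, length.out = 38)
  om <- 0.05
  y <- 0.15 + 0.04 * cos(om * t) - 0.1 * sin(om * t) +
    0.01 * sin(2 * om * t)
  curve <- smooth_ct(concentration_series(t, y, "tissue"), "fourier5")
  parts <- split_and_resample(curve, 20, n = 40L)
  refit <- smooth_ct(parts$stage2, "fourier5")
  probe <- seq(20, 60, length.out = 101)
  expect_lt(max(abs(eval_curve(refit, probe) - eval_curve(curve, probe))),
            1e-6)
})

test_that("weighted ve is the duration-weighted mean", {
  expect_equal(round(weighted_ve(c(1.75, 4.53), c(20, 40)), 1), 3.6)
  expect_equal(weighted_ve(c(1.75, 4.53), c(20, 40)),
               (1.75 * 1 + 4.53 * 2) / 3, tolerance = 1e-12)
  expect_equal(weighted_ve(c(2, 4), c(7, 7)), 3)        # equal durations
  expect_equal(weighted_ve(5.5, 12), 5.5)               # single stage
  # invariance under rescaling all durations
  expect_equal(weighted_ve(c(1, 2, 3), c(1, 2, 3)),
               weighted_ve(c(1, 2, 3), c(10, 20, 30)))
  expect_error(weighted_ve(numeric(0), numeric(0)), "empty")
  expect_error(weighted_ve(c(1, 2), c(1, -1)), "positive")
})

test_that("two-stage fit recovers stage-wise truth within the frozen bounds", {
  # bounds frozen from the noiseless characterization run of this estimator:
  # stage 1 within 5%, stage 2 Ktrans within 10% and Kep within 20%
  # (global-offset mode; smoothing bias dominates stage 2)
  fx <- sim_concentrations(two_stage_design())
  aif <- fit_aif(fx$artery)$params
  for (method in c("fourier5", "linear")) {
    fit <- fit_two_stage(fx$tissue, aif, split_time = 20, method = method)
    expect_lt(rel_err(fit$stage1$params$Ktrans, 0.093), 0.05)
    expect_lt(rel_err(fit$stage1$params$Kep, 0.053), 0.05)
    expect_lt(rel_err(fit$stage2$params$Ktrans, 0.068), 0.10)
    expect_lt(rel_err(fit$stage2$params$Kep, 0.015), 0.20)
    expect_equal(fit$durations[1], 20)
    expect_equal(fit$weighted_ve,
                 weighted_ve(c(fit$stage1$ve, fit$stage2$ve),
                             fit$durations))
  }
})

test_that("with no change at the split both stages agree with the single fit", {
  des <- experiment_design(split_min = 20,
                           truth_stage1 = gkm_params(0.093, 0.053),
                           truth_stage2 = gkm_params(0.093, 0.053))
  fx <- sim_concentrations(des)
  aif <- fit_aif(fx$artery)$params
  fit <- fit_two_stage(fx$tissue, aif, split_time = 20)
  single <- fit_gkm(fx$tissue, aif)
  expect_equal(fit$stage1$params$Ktrans, fit$stage2$params$Ktrans,
               tolerance = 0.02)
  expect_equal(fit$stage1$params$Kep, fit$stage2$params$Kep,
               tolerance = 0.02)
  for (f in list(fit$stage1, fit$stage2)) {
    expect_equal(f$params$Ktrans, single$params$Ktrans, tolerance = 0.02)
    expect_equal(f$params$Kep, single$params$Kep, tolerance = 0.02)
  }
})

test_that("plain GKM underestimates the stage-1 back-transfer under a staged protocol", {
  fx <- sim_concentrations(two_stage_design())
  aif <- fit_aif(fx$artery)$params
  staged <- fit_two_stage(fx$tissue, aif, split_time = 20)
  single <- fit_gkm(fx$tissue, aif)
  expect_lt(single$params$Kep, staged$stage1$params$Kep)
  expect_lt(single$params$Ktrans, staged$stage1$params$Ktrans)
})

test_that("condition summaries normalize to the reference entry", {
  eb <- c(23.85, 57.08, 71.56)
  expect_equal(round(normalize_ratios(eb), 2), c(0.33, 0.80, 1.00))
  expect_equal(normalize_ratios(c(2, 4), reference = 1), c(1, 2))
  expect_error(normalize_ratios(c(1, -2)), "positive")
})
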