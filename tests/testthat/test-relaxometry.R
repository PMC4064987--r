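test_that("no enhancement maps to zero concentration", {
  consts <- default_consts()
  s <- signal_series(c(-2, -1, 0, 5, 10), rep(800, 5), "tissue")
  conc <- signal_to_concentration(s, consts)
  expect_equal(conc$value, rep(0, 5))
  expect_identical(attr(conc, "clamped"), integer(0))
})

test_that("conversion inverts the forward signal model (bisection oracle)", {
  consts <- default_consts()  # TR = 0.5, T10 tissue = 0.9, r1 = 4.62
  ratio <- 1.2
  s <- signal_series(c(-2, -1, 0), c(1000, 1000, 1000 * ratio), "tissue")
  got <- signal_to_concentration(s, consts)$value[3]

  # oracle: bisection on the forward saturation-recovery model in C
  fwd_ratio <- function(C) {
    T1 <- 1 / (1 / 0.9 + 4.62 * C)
    (1 - exp(-0.5 / T1)) / (1 - exp(-0.5 / 0.9))
  }
  oracle <- stats::uniroot(function(C) fwd_ratio(C) - ratio,
                           c(0, 10), tol = 1e-14)$root
  expect_equal(got, oracle, tolerance = 1e-9)
})

test_that("forward and inverse conversions are mutual inverses", {
  for (model in c("saturation_recovery", "linear")) {
    for (comp in c("tissue", "artery")) {
      consts <- default_consts(signal_model = model)
      set.seed(42)
      for (rep in 1:5) {
        n <- 40L
        times <- c(-2, -1, seq(0, 60, length.out = n - 2L)) * 97 / 60
        cvals <- c(0, 0, runif(n - 2L, 0, 0.4))
        conc <- concentration_series(times, cvals, comp)
        sig <- concentration_to_signal(conc, S_pre = 750, consts)
        back <- signal_to_concentration(sig, consts)
        expect_equal(back$value, cvals, tolerance = 1e-9)
        expect_identical(attr(back, "clamped"), integer(0))
      }
    }
  }
})

test_that("round trip holds across 1000 random valid scalar inputs", {
  consts <- default_consts()
  set.seed(7)
  C <- runif(1000, 0, 1.2)  # inside the invertible range for both T10s
  for (comp in c("tissue", "artery")) {
    # vectorized: embed each concentration as the single post-contrast frame
    sig <- concentration_to_signal(
      concentration_series(seq_along(C) - 3, c(0, 0, C[-(1:2)]), comp),
      S_pre = 1000, consts)
    back <- signal_to_concentration(sig, consts)
    expect_equal(back$value[-(1:2)], C[-(1:2)], tolerance = 1e-9)
  }
})

test_that("concentration is monotone in the signal ratio", {
  consts <- default_consts()
  ratios <- seq(1, 2.2, by = 0.05)
  s <- signal_series(c(-2, -1, seq_along(ratios)),
                     c(1, 1, ratios), "tissue")
  conc <- signal_to_concentration(s, consts)$value[-(1:2)]
  expect_true(all(diff(conc) > 0))
})

test_that("artery conversion equals plasma_fraction times unscaled conversion", {
  consts <- default_consts()
  times <- c(-2, -1, 1, 2, 3)
  vals <- c(500, 500, 700, 900, 1100)
  art <- signal_to_concentration(signal_series(times, vals, "artery"), consts)
  # same signals converted with the arterial T10 but no plasma scaling
  unscaled <- default_consts(T10_tissue = consts$T10_artery)
  tis <- signal_to_concentration(signal_series(times, vals, "tissue"),
                                 unscaled)
  expect_equal(art$value, consts$plasma_fraction * tis$value,
               tolerance = 1e-12)
})

test_that("saturated signal ratios are clamped and flagged, not fatal", {
  consts <- default_consts()
  rmax <- 1 / (1 - exp(-consts$TR / consts$T10_tissue))
  s <- signal_series(c(-2, -1, 0, 1), c(1, 1, 1.5, rmax * 1.1), "tissue")
  conc <- signal_to_concentration(s, consts)
  expect_identical(attr(conc, "clamped"), 4L)
  expect_true(is.finite(conc$value[4]))
  expect_gt(conc$value[4], conc$value[3])
})

test_that("invalid conversion inputs are rejected", {
  consts <- default_consts()
  expect_error(
    signal_to_concentration(
      signal_series(c(-2, -1, 0), c(0, 0, 5), "tissue"), consts),
    "positive")
  expect_error(
    concentration_to_signal(
      concentration_series(1:3, c(0, 0.1, 0.2), "tissue"), S_pre = -5,
      consts),
    "S_pre")
  expect_error(
    concentration_to_signal(
      structure(data.frame(time = 1:3, value = c(0, -0.1, 0.2)),
                compartment = "tissue",
                class = c("concentration_series", "data.frame")),
      S_pre = 100, consts),
    "nonnegative")
})

test_that("zero concentration gives constant baseline signal; increasing gives increasing", {
  consts <- default_consts()
  z <- concentration_series(0:4, rep(0, 5), "tissue")
  expect_equal(concentration_to_signal(z, 321, consts)$value, rep(321, 5))
  inc <- concentration_series(0:4, c(0, 0.1, 0.2, 0.4, 0.8), "tissue")
  sig <- concentration_to_signal(inc, 321, consts)$value
  expect_true(all(diff(sig) > 0))
})
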