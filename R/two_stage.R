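#' Smooth a tissue concentration curve
#'
#' Fits a continuous representation of the post-contrast tissue curve, the
#' first step of the two-stage kinetic analysis. Three methods are offered:
#'
#' * `"fourier5"` — least-squares fit of a 5th-order Fourier series
#'   `a0 + sum_{k=1..5} a_k cos(k w t) + b_k sin(k w t)` with the fundamental
#'   angular frequency `w` free (12 parameters). `w` is profiled out: for
#'   fixed `w` the coefficients are a linear solve, and `w` is located by a
#'   grid search plus local refinement, then all 12 parameters are polished
#'   by Levenberg-Marquardt.
#' * `"linear"` — piecewise-linear interpolant through the samples.
#' * `"nearest"` — nearest-neighbour interpolant; an exact midpoint ties to
#'   the earlier sample.
#'
#' @param conc_tissue A [concentration_series()]; `fourier5` needs at least
#'   13 post-contrast samples (one more than its parameter count).
#' @param method `"fourier5"`, `"linear"` or `"nearest"`.
#' @return An object of class `smooth_curve` with fields `method`,
#'   `coefficients` (for `fourier5`: `a0`, `a1..a5`, `b1..b5`, `omega`),
#'   `domain` (time span, minutes) and `rss`. Evaluate it with
#'   [eval_curve()] or `predict()`.
#' @export
smooth_ct <- function(conc_tissue, method = c("fourier5", "linear",
                                              "nearest")) {
  method <- match.arg(method)
  stopifnot(inherits(conc_tissue, "concentration_series"))
  post <- post_contrast(conc_tissue)
  t <- post$time
  y <- post$value
  domain <- range(t)

  if (method == "fourier5") {
    if (length(t) < 13L) {
      stop("fourier5 smoothing needs at least 13 samples (12 parameters)",
           call. = FALSE)
    }
    fit <- fit_fourier5(t, y)
    curve <- structure(
      list(method = method, coefficients = fit$coefficients,
           domain = domain, rss = fit$rss),
      class = "smooth_curve")
  } else {
    curve <- structure(
      list(method = method,
           coefficients = list(knots_t = t, knots_y = y),
           domain = domain, rss = 0),
      class = "smooth_curve")
  }
  curve
}

# 5th-order Fourier series fit with free fundamental frequency.
# Variable projection: coefficients are linear given omega, so omega is
# found by grid + golden-section refinement before a full LM polish.
fit_fourier5 <- function(t, y, order = 5L) {
  span <- diff(range(t))
  design <- function(omega) {
    k <- seq_len(order)
    cbind(1, cos(outer(t, k * omega)), sin(outer(t, k * omega)))
  }
  rss_of <- function(omega) {
    X <- design(omega)
    fit <- stats::lm.fit(X, y)
    sum(fit$residuals^2)
  }
  omega0 <- 2 * pi / (1.2 * span)
  grid <- omega0 * exp(seq(log(0.25), log(4), length.out = 160L))
  rss_grid <- vapply(grid, rss_of, numeric(1))
  i <- which.min(rss_grid)
  lo <- grid[max(1L, i - 1L)]
  hi <- grid[min(length(grid), i + 1L)]
  opt <- stats::optimize(rss_of, c(lo, hi), tol = 1e-12)
  omega <- opt$minimum

  X <- design(omega)
  beta <- stats::lm.fit(X, y)$coefficients
  beta[is.na(beta)] <- 0

  # LM polish on all 12 parameters
  theta0 <- c(beta, omega)
  resid_fn <- function(theta) {
    om <- theta[2L * order + 2L]
    y - design(om) %*% theta[seq_len(2L * order + 1L)]
  }
  fit <- tryCatch(
    minpack.lm::nls.lm(par = theta0, fn = resid_fn,
                       control = minpack.lm::nls.lm.control(
                         maxiter = 500, ftol = 1e-15, ptol = 1e-15)),
    error = function(e) NULL)
  if (!is.null(fit) && sum(fit$fvec^2) <= opt$objective) {
    theta <- fit$par
  } else {
    theta <- theta0
  }
  theta <- unname(theta)
  co <- as.list(theta[seq_len(2L * order + 1L)])
  names(co) <- c("a0", paste0("a", seq_len(order)), paste0("b", seq_len(order)))
  co$omega <- theta[2L * order + 2L]
  list(coefficients = co,
       rss = sum(resid_fn(theta)^2))
}

#' Evaluate a smoothed curve
#'
#' @param curve A `smooth_curve` from [smooth_ct()].
#' @param t Times in minutes; must lie inside the curve's domain.
#' @return Curve values at `t`.
#' @export
eval_curve <- function(curve, t) {
  stopifnot(inherits(curve, "smooth_curve"))
  eps <- 1e-9 * max(1, abs(curve$domain[2]))
  if (any(t < curve$domain[1] - eps | t > curve$domain[2] + eps)) {
    stop(sprintf("evaluation outside curve domain [%.4g, %.4g]",
                 curve$domain[1], curve$domain[2]), call. = FALSE)
  }
  co <- curve$coefficients
  switch(curve$method,
    fourier5 = {
      k <- 1:5
      val <- rep(co$a0, length(t))
      for (kk in k) {
        val <- val + co[[paste0("a", kk)]] * cos(kk * co$omega * t) +
          co[[paste0("b", kk)]] * sin(kk * co$omega * t)
      }
      val
    },
    linear = stats::approx(co$knots_t, co$knots_y, xout = t,
                           rule = 2)$y,
    nearest = {
      # midpoint ties resolve to the earlier sample
      kt <- co$knots_t
      idx <- vapply(t, function(tt) {
        d <- abs(kt - tt)
        which(d <= min(d) + 0e0)[1L]
      }, integer(1))
      co$knots_y[idx]
    })
}

#' @export
predict.smooth_curve <- function(object, t, ...) eval_curve(object, t)

#' @export
print.smooth_curve <- function(x, ...) {
  cat(sprintf("<smooth_curve: %s on [%.3g, %.3g] min, rss = %.4g>\n",
              x$method, x$domain[1], x$domain[2], x$rss))
  invisible(x)
}

#' Split a smoothed curve and resample each part on an equal grid
#'
#' Segments the curve at `split_time` and evaluates it on `n` equally spaced
#' times spanning each closed segment (`[t_start, split]` and
#' `[split, t_end]`); the split point belongs to both grids.
#'
#' @param curve A `smooth_curve`.
#' @param split_time Split point in minutes, strictly inside the domain.
#' @param n Number of resampled points per segment (>= 4; default 40).
#' @return A list with [concentration_series()] elements `stage1` and
#'   `stage2`.
#' @export
split_and_resample <- function(curve, split_time, n = 40L) {
  stopifnot(inherits(curve, "smooth_curve"))
  if (n < 4L) stop("n must be at least 4", call. = FALSE)
  d <- curve$domain
  if (split_time <= d[1] || split_time >= d[2]) {
    stop(sprintf("split time must lie strictly inside [%.4g, %.4g]",
                 d[1], d[2]), call. = FALSE)
  }
  t1 <- seq(d[1], split_time, length.out = n)
  t2 <- seq(split_time, d[2], length.out = n)
  list(
    stage1 = concentration_series(t1, eval_curve(curve, t1), "tissue"),
    stage2 = concentration_series(t2, eval_curve(curve, t2), "tissue")
  )
}

#' Duration-weighted mean of stage-wise ve values
#'
#' `sum(ve_i d_i) / sum(d_i)` for stage durations `d_i`; generalizes to any
#' number of stages and is invariant under rescaling all durations.
#'
#' @param ve_list Numeric vector of stage ve values.
#' @param durations Positive stage durations (minutes), same length.
#' @return The weighted mean (dimensionless).
#' @export
weighted_ve <- function(ve_list, durations) {
  if (length(ve_list) == 0L) stop("empty input", call. = FALSE)
  if (length(ve_list) != length(durations)) {
    stop("ve_list and durations must have the same length", call. = FALSE)
  }
  if (any(durations <= 0)) stop("durations must be positive", call. = FALSE)
  sum(ve_list * durations) / sum(durations)
}

#' Two-stage kinetic analysis of a tissue curve
#'
#' Implements the staged estimator for experiments with a second intervention
#' (e.g. a repeated focused-ultrasound irradiation) at a known time: the
#' tissue curve is smoothed ([smooth_ct()]), segmented at `split_time`,
#' each segment resampled to `n` equally spaced synthetic points
#' ([split_and_resample()]), and stage-wise transfer constants fitted with
#' the shared arterial input, which is always estimated once from all
#' frames.
#'
#' Stage 1 starts at zero concentration and is fitted with the plain model.
#' Stage 2 starts at the carried-over stage-1 concentration, which the plain
#' model cannot represent; two handling modes are offered:
#'
#' * `"global_offset"` (default) — stage 2 is fitted on the global time axis
#'   against the same `Cp(t)` clock, with a free additive constant absorbing
#'   the stage-1 carryover.
#' * `"reorigin"` — stage-2 time is re-origined to the split point and the
#'   concentration at the split subtracted, then the plain model is fitted.
#'
#' @param conc_tissue Tissue [concentration_series()].
#' @param aif Fitted [aif_params()] (from all frames).
#' @param split_time Second-intervention time, minutes, inside the
#'   observation window.
#' @param method Smoothing method, see [smooth_ct()].
#' @param n Resampled points per stage (default 40).
#' @param stage2_mode `"global_offset"` or `"reorigin"`.
#' @return A list of class `two_stage_fit`: `stage1`, `stage2` (each a
#'   `gkm_fit`), `split_time`, `durations`, `weighted_ve`, `method`,
#'   `stage2_mode`, `curve`.
#' @export
fit_two_stage <- function(conc_tissue, aif, split_time,
                          method = c("fourier5", "linear", "nearest"),
                          n = 40L,
                          stage2_mode = c("global_offset", "reorigin")) {
  method <- match.arg(method)
  stage2_mode <- match.arg(stage2_mode)
  stopifnot(inherits(conc_tissue, "concentration_series"),
            inherits(aif, "aif_params"))

  curve <- smooth_ct(conc_tissue, method = method)
  parts <- split_and_resample(curve, split_time, n = n)

  fit1 <- fit_gkm(parts$stage1, aif)
  if (!isTRUE(fit1$converged)) {
    stop("stage 1 kinetic fit failed: ", fit1$message, call. = FALSE)
  }

  if (stage2_mode == "global_offset") {
    fit2 <- fit_gkm(parts$stage2, aif, offset = TRUE)
  } else {
    s2 <- parts$stage2
    base <- s2$value[1L]
    shifted <- concentration_series(s2$time - s2$time[1L],
                                    pmax(s2$value - base, 0), "tissue")
    fit2 <- fit_gkm(shifted, aif)
  }
  if (!isTRUE(fit2$converged)) {
    stop("stage 2 kinetic fit failed: ", fit2$message, call. = FALSE)
  }

  d <- c(split_time - curve$domain[1], curve$domain[2] - split_time)
  wve <- if (isTRUE(fit1$ve_defined) && isTRUE(fit2$ve_defined)) {
    weighted_ve(c(fit1$ve, fit2$ve), d)
  } else {
    NA_real_
  }
  structure(
    list(stage1 = fit1, stage2 = fit2, split_time = split_time,
         durations = d, weighted_ve = wve, method = method,
         stage2_mode = stage2_mode, curve = curve),
    class = "two_stage_fit")
}

#' @export
print.two_stage_fit <- function(x, ...) {
  cat(sprintf("<two_stage_fit: split at %.3g min (%s smoothing, %s)>\n",
              x$split_time, x$method, x$stage2_mode))
  cat(sprintf("  stage 1 (%.3g min): Ktrans = %.4g, Kep = %.4g, ve = %.4g\n",
              x$durations[1], x$stage1$params$Ktrans, x$stage1$params$Kep,
              x$stage1$ve))
  cat(sprintf("  stage 2 (%.3g min): Ktrans = %.4g, Kep = %.4g, ve = %.4g\n",
              x$durations[2], x$stage2$params$Ktrans, x$stage2$params$Kep,
              x$stage2$ve))
  cat(sprintf("  duration-weighted ve = %.4g\n", x$weighted_ve))
  invisible(x)
}

#' Normalize condition-level summaries to a reference condition
#'
#' Expresses a vector of positive quantities (e.g. per-condition dye uptake
#' or ve values) as proportions of a reference entry, the comparison used to
#' relate imaging-derived distribution volumes to ex-vivo dye extraction.
#'
#' @param values Positive numeric vector.
#' @param reference Index of the reference entry (default: the maximum).
#' @return `values / values[reference]`.
#' @export
normalize_ratios <- function(values, reference = which.max(values)) {
  if (length(values) == 0L) stop("empty input", call. = FALSE)
  if (any(values <= 0)) stop("values must be positive", call. = FALSE)
  values / values[[reference]]
}
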