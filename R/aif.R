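#' Biexponential arterial input function parameters
#'
#' The arterial plasma concentration is modeled as
#' `Cp(t) = A1 exp(-m1 t) + A2 exp(-m2 t)` with amplitudes in mM and decay
#' rates in 1/min. Parameters are stored in canonical order `m1 <= m2`
#' (the model is invariant under exchanging the two terms).
#'
#' @param A1,A2 Amplitudes, mM; `A1 + A2` (the modeled peak) must be >= 0.
#' @param m1,m2 Decay rates, 1/min, strictly positive.
#' @return A list of class `aif_params`.
#' @export
aif_params <- function(A1, A2, m1, m2) {
  stopifnot(is.finite(A1), is.finite(A2), is.finite(m1), is.finite(m2))
  if (m1 <= 0 || m2 <= 0) stop("decay rates m1, m2 must be > 0", call. = FALSE)
  if (A1 + A2 < 0) stop("A1 + A2 must be nonnegative", call. = FALSE)
  if (m1 > m2) {  # canonical ordering: slow term first
    tmp <- c(A1, m1); A1 <- A2; m1 <- m2; A2 <- tmp[1]; m2 <- tmp[2]
  }
  structure(list(A1 = A1, A2 = A2, m1 = m1, m2 = m2), class = "aif_params")
}

#' @export
print.aif_params <- function(x, ...) {
  cat(sprintf(
    "<aif_params> Cp(t) = %.4g exp(-%.4g t) + %.4g exp(-%.4g t)  [mM, 1/min]\n",
    x$A1, x$m1, x$A2, x$m2))
  invisible(x)
}

#' Evaluate the biexponential arterial input function
#'
#' @param t Times in minutes, nonnegative.
#' @param params An [aif_params()] object.
#' @return `A1 exp(-m1 t) + A2 exp(-m2 t)` in mM.
#' @export
cp_model <- function(t, params) {
  stopifnot(inherits(params, "aif_params"))
  if (any(t < 0)) stop("cp_model is defined for t >= 0", call. = FALSE)
  params$A1 * exp(-params$m1 * t) + params$A2 * exp(-params$m2 * t)
}

#' Fit the biexponential arterial input function
#'
#' Levenberg-Marquardt least squares on the post-contrast samples
#' (`t >= 0`) of an arterial concentration series. Nonnegativity of all four
#' parameters is enforced by fitting on the log scale. Starting values:
#' `A1 = A2 =` half the peak concentration, `m1 = 1/t_last`,
#' `m2 = 1/t_peak` (floored at one frame interval); if the fit fails to
#' converge, two further attempts are made from deterministically perturbed
#' starts.
#'
#' @param conc A [concentration_series()] for the artery, with at least 8
#'   post-contrast samples.
#' @param max_restarts Number of perturbed-restart attempts after a failed
#'   first fit.
#' @return A list of class `aif_fit` with elements `params`
#'   ([aif_params()] in canonical order), `rss`, `converged`, `n_points`,
#'   `fitted`. If no attempt converges, `converged` is `FALSE` and `params`
#'   holds the best attempt's values.
#' @export
fit_aif <- function(conc, max_restarts = 2L) {
  stopifnot(inherits(conc, "concentration_series"))
  post <- post_contrast(conc)
  t <- post$time
  y <- post$value
  if (length(t) < 8L) {
    stop("need at least 8 post-contrast samples to fit the AIF",
         call. = FALSE)
  }
  if (any(y < 0)) y <- pmax(y, 0)
  peak <- max(y)
  if (peak <= 0) {
    return(structure(
      list(params = NULL, rss = NA_real_, converged = FALSE,
           n_points = length(t), fitted = NULL,
           message = "degenerate series: no enhancement"),
      class = "aif_fit"))
  }

  dt <- min(diff(t))
  t_peak <- max(t[which.max(y)], dt)
  theta0 <- log(c(A1 = peak / 2, A2 = peak / 2,
                  m1 = 1 / max(t), m2 = 1 / t_peak))

  resid_fn <- function(theta) {
    p <- exp(theta)
    y - (p[1] * exp(-p[3] * t) + p[2] * exp(-p[4] * t))
  }

  best <- NULL
  starts <- list(theta0)
  # deterministic perturbations for restarts; caller's RNG state untouched
  for (k in seq_len(max_restarts)) {
    starts[[k + 1L]] <- theta0 +
      with_private_seed(1000L + k, stats::rnorm(4L, sd = 0.5))
  }
  for (theta in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = theta, fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 500, ftol = 1e-14, ptol = 1e-14)),
      error = function(e) NULL)
    if (is.null(fit)) next
    ok <- fit$info %in% 1:4
    rss <- sum(fit$fvec^2)
    if (is.null(best) || (ok && !best$ok) || (ok == best$ok && rss < best$rss)) {
      best <- list(fit = fit, ok = ok, rss = rss)
    }
    if (ok && rss < 1e-12 * sum(y^2)) break
  }

  if (is.null(best)) {
    return(structure(
      list(params = NULL, rss = NA_real_, converged = FALSE,
           n_points = length(t), fitted = NULL,
           message = "optimizer failed on all starts"),
      class = "aif_fit"))
  }
  p <- exp(best$fit$par)
  params <- aif_params(A1 = p[1], A2 = p[2], m1 = p[3], m2 = p[4])
  structure(
    list(params = params, rss = best$rss, converged = best$ok,
         n_points = length(t), fitted = cp_model(t, params),
         message = if (best$ok) "converged" else "did not converge"),
    class = "aif_fit")
}

#' @export
print.aif_fit <- function(x, ...) {
  cat("<aif_fit>", x$message, "\n")
  if (!is.null(x$params)) {
    print(x$params)
    cat(sprintf("  rss = %.4g over %d points\n", x$rss, x$n_points))
  }
  invisible(x)
}
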