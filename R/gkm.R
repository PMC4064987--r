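#' Transfer rate constants of the general kinetic model
#'
#' `Ktrans` (1/min) governs transfer from blood plasma into the extravascular
#' extracellular space; `Kep` (1/min) the back-transfer. Their ratio
#' `ve = Ktrans/Kep` is the distribution-volume parameter.
#'
#' @param Ktrans,Kep Nonnegative rate constants, 1/min.
#' @return A list of class `gkm_params`.
#' @export
gkm_params <- function(Ktrans, Kep) {
  stopifnot(is.finite(Ktrans), is.finite(Kep))
  if (Ktrans < 0 || Kep < 0) {
    stop("Ktrans and Kep must be nonnegative", call. = FALSE)
  }
  structure(list(Ktrans = Ktrans, Kep = Kep), class = "gkm_params")
}

#' @export
print.gkm_params <- function(x, ...) {
  cat(sprintf("<gkm_params> Ktrans = %.4g, Kep = %.4g [1/min]\n",
              x$Ktrans, x$Kep))
  invisible(x)
}

# tolerance below which |m_i - Kep| switches ct_model to the analytic limit
.pole_tol <- 1e-8

#' Closed-form tissue concentration of the general kinetic model
#'
#' With a biexponential arterial input `Cp(t) = sum_i A_i exp(-m_i t)` the
#' convolution `Ct(t) = Ktrans * int_0^t Cp(u) exp(-Kep (t - u)) du` has the
#' closed form
#' `Ktrans * sum_i A_i (exp(-Kep t) - exp(-m_i t)) / (m_i - Kep)`.
#' When `|m_i - Kep|` falls below 1e-8 /min the removable singularity is
#' replaced by its analytic limit `Ktrans A_i t exp(-Kep t)`, keeping the
#' model continuous across the pole.
#'
#' @param t Times in minutes, nonnegative.
#' @param aif An [aif_params()] object.
#' @param params A [gkm_params()] object.
#' @return Tissue concentration in mM at each `t`.
#' @export
ct_model <- function(t, aif, params) {
  stopifnot(inherits(aif, "aif_params"), inherits(params, "gkm_params"))
  if (any(t < 0)) stop("ct_model is defined for t >= 0", call. = FALSE)
  Kt <- params$Ktrans
  Kep <- params$Kep
  term <- function(A, m) {
    if (abs(m - Kep) < .pole_tol) {
      A * t * exp(-Kep * t)
    } else {
      A * (exp(-Kep * t) - exp(-m * t)) / (m - Kep)
    }
  }
  Kt * (term(aif$A1, aif$m1) + term(aif$A2, aif$m2))
}

#' Distribution-volume parameter ve = Ktrans/Kep
#'
#' @param params A [gkm_params()] object with `Kep > 0`, unless
#'   `Ktrans = 0` in which case 0 is returned regardless of `Kep`.
#' @return `Ktrans / Kep` (dimensionless).
#' @export
compute_ve <- function(params) {
  stopifnot(inherits(params, "gkm_params"))
  if (params$Ktrans == 0) return(0)
  if (params$Kep <= 0) {
    stop("ve is undefined for Kep = 0", call. = FALSE)
  }
  params$Ktrans / params$Kep
}

#' Fit the general kinetic model to a tissue concentration series
#'
#' Levenberg-Marquardt least squares for `(Ktrans, Kep)` against
#' [ct_model()] on the post-contrast samples, with the arterial input held
#' fixed at a previously fitted [aif_params()]. Nonnegativity is enforced by
#' optimizing on the log scale. Starting values are
#' `Ktrans = Kep = 0.05` /min, with up to 3 deterministically perturbed
#' restarts on failure.
#'
#' An all-zero tissue series short-circuits to `Ktrans = 0` with `ve`
#' flagged undefined.
#'
#' @param conc_tissue A [concentration_series()] for tissue with >= 6
#'   post-contrast samples.
#' @param aif Fitted [aif_params()].
#' @param offset If `TRUE`, a free additive constant is included in the
#'   model (used by the two-stage estimator to absorb first-stage carryover).
#' @param start Optional numeric starting values `c(Ktrans, Kep)`.
#' @return A list of class `gkm_fit`: `params` ([gkm_params()]), `ve`,
#'   `ve_defined`, `rss`, `converged`, `n_points`, `offset` (fitted constant
#'   or 0), `fitted`.
#' @export
fit_gkm <- function(conc_tissue, aif, offset = FALSE, start = c(0.05, 0.05)) {
  stopifnot(inherits(conc_tissue, "concentration_series"),
            inherits(aif, "aif_params"))
  post <- post_contrast(conc_tissue)
  t <- post$time
  y <- post$value
  if (length(t) < 6L) {
    stop("need at least 6 post-contrast samples to fit the kinetic model",
         call. = FALSE)
  }
  if (max(abs(y)) == 0) {
    return(structure(
      list(params = gkm_params(0, 0), ve = NA_real_, ve_defined = FALSE,
           rss = 0, converged = TRUE, n_points = length(t), offset = 0,
           fitted = rep(0, length(t)), message = "all-zero series"),
      class = "gkm_fit"))
  }

  n_extra <- if (offset) 1L else 0L
  resid_fn <- function(theta) {
    p <- gkm_params(exp(theta[1]), exp(theta[2]))
    mu <- ct_model(t, aif, p)
    if (offset) mu <- mu + theta[3]
    y - mu
  }
  theta0 <- c(log(start), if (offset) 0)

  best <- NULL
  starts <- list(theta0)
  for (k in 1:3) {
    pert <- with_private_seed(2000L + k,
                              stats::rnorm(2L + n_extra, sd = 0.7))
    starts[[k + 1L]] <- theta0 + pert
  }
  for (th in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = th, fn = resid_fn,
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
      list(params = NULL, ve = NA_real_, ve_defined = FALSE, rss = NA_real_,
           converged = FALSE, n_points = length(t), offset = NA_real_,
           fitted = NULL, message = "optimizer failed on all starts"),
      class = "gkm_fit"))
  }
  th <- best$fit$par
  params <- gkm_params(exp(th[1]), exp(th[2]))
  off <- if (offset) th[3] else 0
  ve_defined <- params$Kep > 0 || params$Ktrans == 0
  ve <- if (ve_defined) compute_ve(params) else NA_real_
  mu <- ct_model(t, aif, params) + off
  structure(
    list(params = params, ve = ve, ve_defined = ve_defined,
         rss = best$rss, converged = best$ok, n_points = length(t),
         offset = off, fitted = mu,
         message = if (best$ok) "converged" else "did not converge"),
    class = "gkm_fit")
}

#' @export
print.gkm_fit <- function(x, ...) {
  cat("<gkm_fit>", x$message, "\n")
  if (!is.null(x$params)) {
    cat(sprintf("  Ktrans = %.4g, Kep = %.4g [1/min], ve = %s\n",
                x$params$Ktrans, x$params$Kep,
                if (x$ve_defined) sprintf("%.4g", x$ve) else "undefined"))
    cat(sprintf("  rss = %.4g over %d points\n", x$rss, x$n_points))
    if (x$offset != 0) cat(sprintf("  baseline offset = %.4g mM\n", x$offset))
  }
  invisible(x)
}
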