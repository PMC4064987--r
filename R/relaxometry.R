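#' Acquisition constants for the T1-weighted DCE protocol
#'
#' Bundles the fixed quantities of the acquisition and conversion model.
#' Defaults reproduce a 3T rodent protocol: pre-contrast longitudinal
#' relaxation times T10 of 0.9 s (brain tissue) and 1.5 s (arterial blood),
#' contrast relaxivity r1 = 4.62 /mM/s, a 0.55 plasma fraction applied to the
#' arterial concentration, TR = 0.5 s, 97-s frame interval and 2 pre-contrast
#' frames.
#'
#' @param T10_tissue Pre-contrast T1 of brain tissue, seconds.
#' @param T10_artery Pre-contrast T1 of arterial blood, seconds.
#' @param r1 Longitudinal relaxivity of the contrast agent, 1/(mM s).
#' @param plasma_fraction Fraction of blood volume that is plasma, in (0, 1].
#'   The arterial concentration is multiplied by this value.
#' @param TR Repetition time of the T1-weighted sequence, seconds.
#' @param frame_interval Time between consecutive frames, seconds.
#' @param n_precontrast_frames Number of frames acquired before contrast
#'   injection; their mean defines the baseline signal.
#' @param signal_model `"saturation_recovery"` (default) solves the nonlinear
#'   spin-echo signal equation S ~ 1 - exp(-TR/T1) per frame;
#'   `"linear"` uses the small-enhancement linearization
#'   C = (S_post/S_pre - 1)/(r1 T10).
#' @return A list of class `acquisition_constants`.
#' @export
acquisition_constants <- function(T10_tissue = 0.9,
                                  T10_artery = 1.5,
                                  r1 = 4.62,
                                  plasma_fraction = 0.55,
                                  TR = 0.5,
                                  frame_interval = 97,
                                  n_precontrast_frames = 2L,
                                  signal_model = c("saturation_recovery",
                                                   "linear")) {
  signal_model <- match.arg(signal_model)
  stopifnot(
    T10_tissue > 0, T10_artery > 0, r1 > 0, TR > 0, frame_interval > 0,
    plasma_fraction > 0, plasma_fraction <= 1,
    n_precontrast_frames >= 0
  )
  structure(
    list(
      T10_tissue = T10_tissue, T10_artery = T10_artery, r1 = r1,
      plasma_fraction = plasma_fraction, TR = TR,
      frame_interval = frame_interval,
      n_precontrast_frames = as.integer(n_precontrast_frames),
      signal_model = signal_model
    ),
    class = "acquisition_constants"
  )
}

#' @export
print.acquisition_constants <- function(x, ...) {
  cat("<acquisition_constants>\n")
  cat(sprintf("  T10 tissue/artery: %.3g / %.3g s;  r1: %.3g /mM/s\n",
              x$T10_tissue, x$T10_artery, x$r1))
  cat(sprintf("  plasma fraction: %.2f;  TR: %.3g s;  frame interval: %.3g s\n",
              x$plasma_fraction, x$TR, x$frame_interval))
  cat(sprintf("  pre-contrast frames: %d;  signal model: %s\n",
              x$n_precontrast_frames, x$signal_model))
  invisible(x)
}

t10_for <- function(consts, compartment) {
  switch(compartment,
         tissue = consts$T10_tissue,
         artery = consts$T10_artery,
         stop("unknown compartment: ", compartment, call. = FALSE))
}

# Largest signal ratio the saturation-recovery model can produce at a given
# T10: S/S_pre -> 1/(1 - exp(-TR/T10)) as T1 -> 0.
ratio_asymptote <- function(TR, T10) 1 / (1 - exp(-TR / T10))

#' Convert MRI signal intensities to contrast-agent concentration
#'
#' The baseline S_pre is the arithmetic mean of the first
#' `n_precontrast_frames` samples. Under the saturation-recovery model each
#' frame's T1 solves
#' `S_post/S_pre = (1 - exp(-TR/T1)) / (1 - exp(-TR/T10))`,
#' and the concentration is `C = (1/T1 - 1/T10)/r1`. Under the linear model
#' `C = (S_post/S_pre - 1)/(r1 T10)`. For the artery the result is multiplied
#' by `plasma_fraction`, since the agent is confined to plasma; tissue is not
#' scaled. Pre-contrast frames map to concentration 0.
#'
#' Signal ratios at or beyond the saturation asymptote (where no finite T1
#' exists) are clamped to 99.9% of the asymptote; the affected frame indices
#' are returned in attribute `clamped`, so noisy frames never abort a fit.
#'
#' @param signal A [signal_series()].
#' @param consts An [acquisition_constants()] object.
#' @return A [concentration_series()] for the same compartment and time grid,
#'   with attribute `clamped` (integer indices of clamped frames).
#' @export
signal_to_concentration <- function(signal, consts = acquisition_constants()) {
  stopifnot(inherits(signal, "signal_series"),
            inherits(consts, "acquisition_constants"))
  comp <- series_compartment(signal)
  n_pre <- consts$n_precontrast_frames
  if (n_pre < 1L) {
    stop("need at least one pre-contrast frame to define the baseline",
         call. = FALSE)
  }
  if (nrow(signal) <= n_pre) {
    stop("series has no post-contrast frames", call. = FALSE)
  }
  s_pre <- mean(signal$value[seq_len(n_pre)])
  if (!is.finite(s_pre) || s_pre <= 0) {
    stop("pre-contrast baseline signal must be strictly positive",
         call. = FALSE)
  }
  T10 <- t10_for(consts, comp)
  ratio <- signal$value / s_pre

  clamped <- integer(0)
  if (consts$signal_model == "saturation_recovery") {
    rmax <- ratio_asymptote(consts$TR, T10)
    over <- which(ratio >= rmax * (1 - 1e-3))
    if (length(over)) {
      ratio[over] <- rmax * (1 - 1e-3)
      clamped <- over
    }
    # invert S/Spre = (1 - exp(-TR/T1)) / (1 - exp(-TR/T10)) for 1/T1
    rhs <- 1 - ratio * (1 - exp(-consts$TR / T10))
    inv_T1 <- -log(rhs) / consts$TR
    conc <- (inv_T1 - 1 / T10) / consts$r1
  } else {
    conc <- (ratio - 1) / (consts$r1 * T10)
  }
  if (comp == "artery") conc <- conc * consts$plasma_fraction

  post <- seq.int(n_pre + 1L, nrow(signal))
  conc[seq_len(n_pre)] <- 0
  clamped <- setdiff(clamped, seq_len(n_pre))
  out <- concentration_series(signal$time, conc, compartment = comp)
  attr(out, "clamped") <- as.integer(clamped)
  attr(out, "S_pre") <- s_pre
  out
}

#' Convert a concentration series to MRI signal intensities
#'
#' Exact functional inverse of [signal_to_concentration()] on valid inputs:
#' the per-frame T1 is `1/T1 = 1/T10 + r1 C` and the signal is
#' `S = S_pre (1 - exp(-TR/T1)) / (1 - exp(-TR/T10))` (saturation-recovery
#' model) or `S = S_pre (1 + r1 T10 C)` (linear model). Arterial
#' concentrations are divided by `plasma_fraction` before inversion, undoing
#' the plasma scaling applied in the forward direction.
#'
#' @param conc A [concentration_series()]; values must be nonnegative.
#' @param S_pre Baseline (pre-contrast) signal, arbitrary units, > 0.
#' @param consts An [acquisition_constants()] object.
#' @return A [signal_series()] on the same time grid.
#' @export
concentration_to_signal <- function(conc, S_pre,
                                    consts = acquisition_constants()) {
  stopifnot(inherits(conc, "concentration_series"),
            inherits(consts, "acquisition_constants"))
  if (!is.finite(S_pre) || S_pre <= 0) {
    stop("S_pre must be strictly positive", call. = FALSE)
  }
  if (any(conc$value < 0)) {
    stop("concentrations must be nonnegative", call. = FALSE)
  }
  comp <- series_compartment(conc)
  T10 <- t10_for(consts, comp)
  cval <- conc$value
  if (comp == "artery") cval <- cval / consts$plasma_fraction

  if (consts$signal_model == "saturation_recovery") {
    inv_T1 <- 1 / T10 + consts$r1 * cval
    sig <- S_pre * (1 - exp(-consts$TR * inv_T1)) /
      (1 - exp(-consts$TR / T10))
  } else {
    sig <- S_pre * (1 + consts$r1 * T10 * cval)
  }
  signal_series(conc$time, sig, compartment = comp)
}
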