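#' Design of a simulated DCE-MRI experiment
#'
#' Describes the acquisition schedule and ground-truth kinetics of a
#' simulated experiment. Defaults emulate the 40-frame protocol: 97 s per
#' frame, 2 pre-contrast frames, hence 38 post-contrast frames covering
#' about one hour after injection. A two-stage design (repeated
#' intervention) is requested by supplying both `split_min` and
#' `truth_stage2`; the transfer constants then switch at `split_min` while
#' the tissue curve stays continuous.
#'
#' The default ground truth uses condition-mean transfer constants from the
#' repeated-irradiation experiment (stage 1: Ktrans 0.093, Kep 0.053; stage
#' 2: Ktrans 0.068, Kep 0.015 /min) and a biexponential arterial input with
#' an apparent sampled peak of 0.25 mM, a fast distribution phase
#' (half-life ~1.4 min) and a slow elimination tail (half-life ~35 min).
#' The low apparent peak reflects what an arterial ROI actually reports at
#' this resolution: a 97-s frame interval misses the first-pass bolus, and
#' the small-vessel ROI is heavily partial-volume diluted. It also keeps
#' both compartments inside the invertible (unsaturated) range of the
#' T1-weighted signal model, so conversion round-trips are well posed.
#'
#' @param n_frames Total frames (default 40).
#' @param frame_interval Seconds between frames (default 97).
#' @param n_precontrast Pre-contrast frames (default 2).
#' @param truth_aif [aif_params()] ground truth for the arterial input.
#' @param truth_stage1 [gkm_params()] ground truth (single-stage truth, or
#'   stage-1 truth for two-stage designs).
#' @param split_min Time of the second intervention in minutes, or `NULL`
#'   for a single-stage design.
#' @param truth_stage2 [gkm_params()] for the second stage, or `NULL`.
#' @return A list of class `experiment_design` with the frame-time grid in
#'   minutes (`t = 0` at the first post-contrast frame).
#' @export
experiment_design <- function(n_frames = 40L,
                              frame_interval = 97,
                              n_precontrast = 2L,
                              truth_aif = aif_params(A1 = 0.10, A2 = 0.15,
                                                     m1 = 0.02, m2 = 0.5),
                              truth_stage1 = gkm_params(Ktrans = 0.093,
                                                        Kep = 0.053),
                              split_min = NULL,
                              truth_stage2 = NULL) {
  stopifnot(n_frames >= n_precontrast + 3L, frame_interval > 0,
            inherits(truth_aif, "aif_params"),
            inherits(truth_stage1, "gkm_params"))
  if (is.null(split_min) != is.null(truth_stage2)) {
    stop("split_min and truth_stage2 must be supplied together",
         call. = FALSE)
  }
  dt <- frame_interval / 60  # minutes
  times <- (seq_len(n_frames) - n_precontrast - 1L) * dt
  if (!is.null(split_min)) {
    stopifnot(inherits(truth_stage2, "gkm_params"))
    if (split_min <= 0 || split_min >= max(times)) {
      stop("split_min must fall inside the post-contrast window",
           call. = FALSE)
    }
  }
  structure(
    list(n_frames = as.integer(n_frames), frame_interval = frame_interval,
         n_precontrast = as.integer(n_precontrast), times = times,
         truth_aif = truth_aif, truth_stage1 = truth_stage1,
         split_min = split_min, truth_stage2 = truth_stage2),
    class = "experiment_design")
}

#' Noise model for simulated signals
#'
#' @param kind `"none"`, `"gaussian"` (additive), or `"rician"` (magnitude
#'   of a complex signal with independent Gaussian noise on both channels,
#'   the physically correct model for magnitude MR images).
#' @param sigma Noise standard deviation as a fraction of the series' peak
#'   signal.
#' @param seed Integer seed; generation is bit-reproducible.
#' @return A list of class `noise_model`.
#' @export
noise_model <- function(kind = c("none", "gaussian", "rician"),
                        sigma = 0, seed = 1L) {
  kind <- match.arg(kind)
  stopifnot(sigma >= 0)
  structure(list(kind = kind, sigma = sigma, seed = as.integer(seed)),
            class = "noise_model")
}

#' Simulate arterial and tissue concentration curves
#'
#' The arterial curve is the biexponential [cp_model()] at the design's
#' truth parameters (zero on pre-contrast frames). The tissue curve solves
#' `dCt/dt = Ktrans(t) Cp(t) - Kep(t) Ct` by ODE integration
#' (`deSolve::lsoda` at tight tolerance), with the stage-active constants
#' switching at `split_min` for two-stage designs; integration keeps the
#' tissue curve continuous at the switch, as physical concentration cannot
#' jump. For single-stage designs the integrated curve agrees with the
#' closed-form [ct_model()].
#'
#' @param design An [experiment_design()].
#' @return List with [concentration_series()] elements `artery` and
#'   `tissue` on the design's frame grid.
#' @export
simulate_concentrations <- function(design) {
  stopifnot(inherits(design, "experiment_design"))
  times <- design$times
  post <- times[times >= 0]
  cp <- ifelse(times < 0, 0, cp_model(pmax(times, 0), design$truth_aif))

  ct_post <- integrate_tissue(post, design)
  ct <- ifelse(times < 0, 0, NA_real_)
  ct[times >= 0] <- ct_post

  list(
    artery = concentration_series(times, cp, "artery"),
    tissue = concentration_series(times, ct, "tissue")
  )
}

# Piecewise ODE integration of the tissue compartment on arbitrary
# nonnegative output times. Two-stage designs are integrated segment by
# segment so the solver never steps across the rate discontinuity.
integrate_tissue <- function(t_out, design, rtol = 1e-11, atol = 1e-13) {
  aif <- design$truth_aif
  split <- design$split_min
  deriv_for <- function(p) {
    function(t, y, parms) list(p$Ktrans * cp_model(t, aif) - p$Kep * y)
  }
  run <- function(times, y0, p) {
    deSolve::lsoda(y = c(ct = y0), times = times, func = deriv_for(p),
                   parms = NULL, rtol = rtol, atol = atol)
  }
  if (is.null(split)) {
    tt <- sort(unique(c(0, t_out)))
    sol <- run(tt, 0, design$truth_stage1)
    return(unname(sol[match(t_out, sol[, "time"]), "ct"]))
  }
  t1 <- sort(unique(c(0, t_out[t_out <= split], split)))
  sol1 <- run(t1, 0, design$truth_stage1)
  c_split <- unname(sol1[nrow(sol1), "ct"])
  t2 <- sort(unique(c(split, t_out[t_out > split])))
  sol2 <- run(t2, c_split, design$truth_stage2)
  ct <- numeric(length(t_out))
  i1 <- t_out <= split
  ct[i1] <- sol1[match(t_out[i1], sol1[, "time"]), "ct"]
  ct[!i1] <- sol2[match(t_out[!i1], sol2[, "time"]), "ct"]
  ct
}

#' Simulate a full signal-domain dataset
#'
#' Converts simulated concentrations to T1-weighted signals through
#' [concentration_to_signal()], applies the noise model (seeded,
#' bit-reproducible, without disturbing the caller's RNG state) and returns
#' the tabular dataset that the readers/writers understand.
#'
#' @param design An [experiment_design()].
#' @param noise A [noise_model()].
#' @param consts An [acquisition_constants()].
#' @param S_pre_artery,S_pre_tissue Baseline signal levels (arbitrary
#'   units).
#' @return A data frame with columns `time_min`, `artery_signal`,
#'   `tissue_signal`, carrying the design and constants as attributes.
#' @export
simulate_signals <- function(design, noise = noise_model(),
                             consts = acquisition_constants(),
                             S_pre_artery = 500, S_pre_tissue = 1000) {
  stopifnot(inherits(design, "experiment_design"),
            inherits(noise, "noise_model"))
  conc <- simulate_concentrations(design)
  sig_a <- concentration_to_signal(conc$artery, S_pre_artery, consts)
  sig_t <- concentration_to_signal(conc$tissue, S_pre_tissue, consts)

  va <- apply_noise(sig_a$value, noise, stream = 1L)
  vt <- apply_noise(sig_t$value, noise, stream = 2L)

  out <- data.frame(time_min = design$times,
                    artery_signal = va,
                    tissue_signal = vt)
  attr(out, "design") <- design
  attr(out, "consts") <- consts
  out
}

apply_noise <- function(values, noise, stream = 1L) {
  if (noise$kind == "none" || noise$sigma == 0) return(values)
  sd_abs <- noise$sigma * max(values)
  n <- length(values)
  with_private_seed(noise$seed * 10L + stream, {
    switch(noise$kind,
      gaussian = values + stats::rnorm(n, sd = sd_abs),
      rician = {
        re <- values + stats::rnorm(n, sd = sd_abs)
        im <- stats::rnorm(n, sd = sd_abs)
        sqrt(re^2 + im^2)
      })
  })
}
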