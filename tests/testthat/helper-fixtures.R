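# Shared fixture builders. Everything is generated in code at test time.

default_consts <- function(...) acquisition_constants(...)

# Simulated noiseless dataset converted back to concentration series.
sim_concentrations <- function(design, consts = default_consts()) {
  sim <- simulate_signals(design, noise_model(), consts)
  list(
    artery = signal_to_concentration(
      signal_series(sim$time_min, sim$artery_signal, "artery"), consts),
    tissue = signal_to_concentration(
      signal_series(sim$time_min, sim$tissue_signal, "tissue"), consts),
    design = design
  )
}

single_stage_design <- function(Ktrans = 0.126, Kep = 0.044) {
  experiment_design(truth_stage1 = gkm_params(Ktrans, Kep))
}

two_stage_design <- function() {
  experiment_design(split_min = 20,
                    truth_stage1 = gkm_params(0.093, 0.053),
                    truth_stage2 = gkm_params(0.068, 0.015))
}

# Independent quadrature oracle for the tissue curve: direct numerical
# convolution of the arterial input with the exponential kernel.
ct_quadrature <- function(t, aif, params, rel.tol = 1e-12) {
  vapply(t, function(tt) {
    if (tt == 0) return(0)
    params$Ktrans * stats::integrate(
      function(u) cp_model(u, aif) * exp(-params$Kep * (tt - u)),
      lower = 0, upper = tt, rel.tol = rel.tol, abs.tol = 0,
      subdivisions = 500L)$value
  }, numeric(1))
}

rel_err <- function(est, truth) abs(est - truth) / abs(truth)
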