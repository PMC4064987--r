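# dcegkm

Kinetic modeling of blood-brain-barrier (BBB) permeability from dynamic
contrast-enhanced MRI (DCE-MRI) time series, for experiments in which the
barrier is opened by focused ultrasound — including **repeated** openings
within one scan session.

## Who this is for

Labs quantifying ultrasound-induced BBB disruption (or any acute
permeability change) from ROI-averaged T1-weighted DCE time courses. The
package covers the full desk-side pipeline: signal-to-concentration
conversion, arterial input function (AIF) fitting, single and staged
kinetic fits, and a forward simulator so every estimator can be validated
without scan data.

## The model

The two-compartment general kinetic model (Tofts model) links the arterial
plasma concentration `Cp(t)` to the tissue concentration `Ct(t)`:

    dCt/dt = Ktrans * Cp(t) - Kep * Ct(t)

`Ktrans` (1/min) is the plasma-to-tissue transfer constant — the
permeability readout, near zero for an intact BBB — and `Kep` (1/min) the
back-transfer constant; `ve = Ktrans/Kep` is the distribution-volume
parameter. With a biexponential AIF `Cp(t) = A1 exp(-m1 t) + A2 exp(-m2 t)`
the tissue curve has a closed form, fitted by Levenberg-Marquardt.

When the barrier is opened a second time at a known moment (a second
microbubble dose plus irradiation), one `(Ktrans, Kep)` pair cannot follow
the tissue curve and underestimates the kinetics. The **two-stage
estimator** smooths the tissue curve with a free-frequency 5th-order
Fourier series, splits it at the second-intervention time, resamples each
segment at 40 equally spaced points, fits stage-wise constants against the
shared AIF (always estimated once from all frames), and reports a
duration-weighted mean `ve`.

## Worked example

Simulate a repeated-opening experiment (40 frames, 97 s apart, 2
pre-contrast; kinetics switch at 20 min), convert, and fit:

```r
library(dcegkm)

des <- experiment_design(split_min = 20,
                         truth_stage1 = gkm_params(0.093, 0.053),
                         truth_stage2 = gkm_params(0.068, 0.015))
sim <- simulate_signals(des, noise_model("gaussian", sigma = 0.01, seed = 42))

cp  <- signal_to_concentration(signal_series(sim$time_min, sim$artery_signal, "artery"))
ct  <- signal_to_concentration(signal_series(sim$time_min, sim$tissue_signal, "tissue"))
aif <- fit_aif(cp)
fit <- fit_two_stage(ct, aif$params, split_time = 20)
fit
#> <two_stage_fit: split at 20 min (fourier5 smoothing, global_offset)>
#>   stage 1 (20 min): Ktrans = 0.08981, Kep = 0.05076, ve = 1.769
#>   stage 2 (39.8 min): Ktrans = 0.07891, Kep = 0.01551, ve = 5.087
#>   duration-weighted ve = 3.978
```

Stage-wise estimates sit close to the simulation truth despite 1% signal
noise. A single fit over the whole curve, by contrast, underestimates the
stage-1 kinetics:

```r
fit_gkm(ct, aif$params)
#> <gkm_fit> converged
#>   Ktrans = 0.0673, Kep = 0.01641 [1/min], ve = 4.101
```

`Ktrans` 0.067 vs the true first-stage 0.093 — the staged analysis exists
precisely to avoid this bias. `weighted_ve()` summarizes stage values
(e.g. `weighted_ve(c(1.75, 4.53), c(20, 40))` → 3.60), and
`normalize_ratios()` expresses condition means as proportions of a
reference condition for comparison with ex-vivo dye extraction.

A YAML-driven pipeline (`run_pipeline()`) and a thin CLI
(`inst/cli/dcegkm.R`, subcommands `simulate | convert | fit-gkm |
fit-two-stage | report`) wrap the same functions; see
`inst/extdata/two_stage_config.yaml` for a complete configuration.

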