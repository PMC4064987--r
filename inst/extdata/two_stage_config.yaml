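# Example configuration for a staged (repeated-intervention) analysis.
mode: two_stage
acquisition:
  T10_tissue: 0.9        # s, pre-contrast T1 of brain tissue
  T10_artery: 1.5        # s, pre-contrast T1 of arterial blood
  r1: 4.62               # /mM/s, contrast relaxivity at 3T
  plasma_fraction: 0.55  # arterial concentration scaling
  TR: 0.5                # s
  frame_interval: 97     # s
  n_precontrast_frames: 2
  signal_model: saturation_recovery
two_stage:
  split_min: 20          # second-intervention time, minutes
  smoothing: fourier5    # fourier5 | linear | nearest
  n_resample: 40
  stage2_mode: global_offset
design:                  # used by `simulate`, or when io.input is absent
  split_min: 20
  truth_stage1: {Ktrans: 0.093, Kep: 0.053}
  truth_stage2: {Ktrans: 0.068, Kep: 0.015}
noise:
  kind: gaussian
  sigma: 0.01            # fraction of peak signal
  seed: 1
io:
  input: null            # set to a CSV path to analyze real data
  output: report.json
  plot: fit.png
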