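geometry:
  lattice_spacing_nm: 88.0
  cell_diameter_nm: 630.0
  cell_length_nm: 2200.0
  bin_size_bp: 10000.0
  monomers_per_region: 2.0
sampler:
  n_samples: 2000.0
  thin_sweeps: ~
  burn_in: ~
fit:
  max_iter: 80.0
  n_samples: 2000.0
  n_samples_final: 8000.0
  step0: 0.6
  tol_deviation_pct: 6.0
  tol_pearson: 0.998
  tol_residual: 0.01
  mask_band: 1.0
  zero_policy: exclude
analysis:
  sud_radius: 2.0
  sud_min_size: 5.0
  info_bias: miller_madow
seed: 1.0
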