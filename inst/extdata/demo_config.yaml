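# Demo configuration for `gesse all` / run_all().
# Synthetic values throughout; the callosum histograms are the shipped
# synthetic defaults, not measured electron-microscopy data.
seed: 42
phantom:
  dim: [48, 56, 40]
  voxel_size_mm: [2.0, 2.0, 2.0]
  n_tracts: 8
  tract_voxels: 150
  noise_sigma: 0.0
estimate:
  n_min: 6
  n_max: 11
  method: pair
orientation:
  coeffs: [22.08, -6.06, 3.49, 0.0]
  sigma: 1.5
  tract_voxels: 2500
  kappa: 8.0
  fa_min: 0.4
  prob_min: 0.25
callosum:
  histogram_csv: null
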