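# Example end-to-end configuration: simulate traces with an MA(2) spatial
# kernel, render + segment a microscopy-like frame, then compute spatial and
# cluster statistics. Run with:
#   Rscript inst/scripts/filament-pipeline.R run --config inst/extdata/demo-config.yaml --out demo_out
seed: 1
output_dir: demo_out
stages: [simulate, render, segment, stats, clusters]
simulate:
  n_filaments: 12
  length_min: 8
  length_max: 24
  baseline_mean: 13.0
  filament_cv: 0.09
  within_kernel: [1, 1, 1]
  cell_noise_sd: 1.0
render:
  image_size: [300, 460]
segment:
  typical_cell_area: 25
  neighbor_max_gap: 14
stats:
  n_max: 6
  n_permutations: 10
  min_length: 8
clusters:
  percentile: 0.15
  null_p: 0.15
  null_n: 1000
  null_len: 20
  n_boot: 1000
plots: true
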