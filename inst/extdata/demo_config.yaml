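# Bundled demonstration configuration: three synthetic TMA slides of 43
# annotated cores each (~130 cores at an 8:1 tumour:normal imbalance, plus a
# reference kidney core per slide), a 60-peak panel with 5 marker features at
# a 2-fold tumour effect, log-normal pixel noise sd 0.3, per-slide batch
# factors of log-sd 0.3 and 2 ppm run-to-run mass-axis jitter.
simulation:
  n_slides: 3
  cores_per_slide: 43
  tumour_fraction: 0.8889
  n_features: 60
  n_markers: 5
  marker_log2_effect: 1.0
  slide_batch_sd: 0.3
  ppm_jitter_sd: 2.0
  noise_sd: 0.3
  core_radius_px: 2
  pixel_size_um: 85
  snr_floor: 1.0
  seed: 1
preprocess:
  snr_min: 3
  ppm_tol: 10
  kmeans_k: 4
  kmeans_seed: 1
K: 10
seed: 1
lambda: 0.01
threshold: 0.5
alpha: 0.05
select_features: true
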