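# Demo: synthetic 20-ROI phantom, full pipeline with bootstrap
phantom: four_cluster
noise_sd: 10
simulate_volume: false
reference_roi: 1
n_average: 1
threshold: 0.4
seed: 7
out_dir: glymclust_demo
infusion:
  rate: 1.0
  volume: 10.0
  start_time: 5.0
bootstrap:
  n_boot: 200
  scales: [0.6, 0.8, 1.0, 1.2, 1.4]
  seed: 7
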