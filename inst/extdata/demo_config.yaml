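# Demo run: two conditions (control, ROS-scavenger NAC) with three
# replicate chambers ("mice") each, 2000 droplets per chamber, six frames
# at 10 min intervals, trace-level simulation.
seed: 7
image_level: false
chamber:
  n_droplets: 2000
  droplet_volume: 5.0e-11
  lambda_occupancy: 0.3
acquisition:
  n_frames: 6
  interval_s: 600
  noise_sd: 5
conditions:
  - name: control
    n_replicates: 3
    nox_fraction: 0.3
  - name: NAC
    n_replicates: 3
    nox_fraction: 0.3
threshold:
  mode: fixed
  threshold_pct: 10.3
constants:
  igg_upper: 285
rna:
  enabled: true
  n_cells: 1000
  nox_positive_fraction: 0.25
  noise_sd: 0.3
make_figures: false
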