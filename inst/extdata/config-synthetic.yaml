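# Bundled example configuration: a synthetic plane cohort whose waves all
# travel at 5 mm/min, so the pipeline summary should report success for every
# event and velocity estimates of 5 +/- 1 mm/min.
subject: SYN1
seed: 42
synthetic:
  n_events: 4
  mesh_kind: plane
  spacing: 1
  velocity_range: [5, 5]
  wave_radius: 2
  p_branching: 0
params:
  patch_radius: 30
  r_max: 5
validate: true
heatmaps: false
log_level: info
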