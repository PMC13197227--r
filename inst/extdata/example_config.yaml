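# Example pipeline configuration: a small GHL17-protonema run.
phantom:
  condition: ghl17_proto
  seed: 1
  box_voxels: [128, 128, 128]
  noise_snr: 5
geometry:
  interval_nm: 2
  expansion_positions: 11
  expansion_radius_nm: 15   # coat-surface radius of the preset
  filter_min_dist_nm: 8
alignment:
  angular_step_deg: 30
output_dir: pdtomo_run
master_seed: 11
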