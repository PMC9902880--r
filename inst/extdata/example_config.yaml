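# Example run configuration: 10 pM target detection scenario at desk scale.
scenario: target
assay:
  probe1_surface_density: 0.15
  probe2_conc: 1.0e-8
  target_conc: 1.0e-11
imaging:
  width: 128
  height: 128
  n_frames: 30
  photons_per_frame: 600
detection:
  threshold_k: 5
  min_separation: 4
trace:
  aperture_radius: 3
quantification:
  mode: counting
n_regions: 3
output_dir: smicount-run
seed: 42
write_movies: false
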