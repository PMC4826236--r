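# Demo run: two simulated arms (control vs treated chromatin texture),
# segmentation, per-nucleus GLCM features, per-sample means, percent
# change, chromatin-pattern call and per-feature Mann-Whitney tests.
seed: 11
output_dir: chromtex_demo_out
simulate:
  n_samples: 3
  scene:
    height: 256
    width: 256
    n_nuclei: 12
  control:
    texture_regime: control
  treated:
    texture_regime: treated
    clumpiness: 0.4
glcm:
  levels: 32
  distance: 1
  angles: [0, 45, 90, 135]
  symmetric: true
  average_over_angles: true
segmentation:
  smoothing_sigma: 2
  min_area: 100
  max_area: 10000
pattern_threshold: 5
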