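# Nuclei counting, other-body-parts parameter set (ball scales 1-3 step 1).
seed: 1
input: {phantom: nuclei, n: 100, dim: [128, 128, 128], snr: 10}
stages:
  - {op: gaussian_smooth, sigma: 1}
  - {op: ballness, stddev_min: 1, stddev_max: 3, stddev_step: 1}
  - {op: binarize}
  - {op: remove_small_spots, min_voxels: 20}
  - {op: watershed, h: 1}
  - {op: count_labels}
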