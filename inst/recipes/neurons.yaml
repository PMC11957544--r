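# Neuron counting: sparse markers, enhancement scales 2-5 step 1.
seed: 1
input: {phantom: nuclei, n: 40, dim: [128, 128, 128], snr: 8,
        radius_range: [4, 6]}
stages:
  - {op: anisotropic_diffusion, n_iterations: 5}
  - {op: ballness, stddev_min: 2, stddev_max: 5, stddev_step: 1}
  - {op: binarize}
  - {op: remove_small_spots, min_voxels: 20}
  - {op: watershed, h: 1}
  - {op: count_labels}
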