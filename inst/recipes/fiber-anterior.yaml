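# Anterior muscle-fiber tracing: cylinder length 18, outer radius 2.8,
# mask radius 3, angular sampling 5 degrees.
seed: 1
input: {phantom: fibers, n: 8, dim: [96, 96, 96], snr: 5}
stages:
  - {op: unsharp_mask, sigma: 2, amount: 1}
  - {op: cylinder_correlate, length: 18, outer_radius: 2.8, mask_radius: 3,
     angular_step: 5, min_intensity: 0.35}
  - {op: trace_correlation_lines, seed_threshold: 0.5, min_length: 10}
  - {op: classify_orientation}
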