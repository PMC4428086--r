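# Example run configuration. Anything omitted falls back to the canonical
# defaults (shown here explicitly for reference).
region:
  core_threshold: 0.25
  surface_threshold: 0.40
  salt_cutoff: 4.5
  probe: 1.4
  max_turn_len: 6
geometry:
  rotation: 9
  rise: 5.0
  packing: 3.0
solver:
  grid_points: 257
  spacing: 1.0
  temperature: 300
  a: 2.8
  p0: 3.00
  C_dip: 55
  salt: 0
  residual_tol: 1.0e-6
policy: amylin_2015
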