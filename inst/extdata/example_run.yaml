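# Example run configuration: desk-scale evolution under a square-wave
# glucose supply with no competition for glucose.
# Units: min, mM, L. Any key omitted falls back to its default.
preset: ncg_square_T40
simulation:
  N0: 10000
  N_star: 500
  N_tr: 50
  t_s: 0
  t_ms: 3000
  t_me: 52000
  t_e: 62000
  track_start: 61600
environment:
  d: 1.0e-5   # provisional removal constant; calibrate before the run
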