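# Example run configuration; omitted fields take package defaults.
optical:
  wavelength: 488
  n_glass: 1.515
  n_water: 1.33
  numerical_aperture: 1.45
camera:
  em_gain: 50
  read_noise: 10
  black_level: 100
speckle:
  contrast: 0.3
scenario:
  name: puff_depths
processing:
  deinterleave: 2
  f0_floor: 1
analysis:
  lo: 0.9
  hi: 1.1
  min_events: 4
seed: 1
out_dir: results
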