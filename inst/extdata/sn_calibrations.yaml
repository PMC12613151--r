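# Per-class exponential sn-ratio calibrations: ratio(f) = c1 * exp(c2 * f)
# with f the SNA isomer fraction. Published coefficients from calibration
# mixtures of sn-isomer standard pairs at seven SNA:SNB mixing ratios
# (1:8 ... 8:1); PC pooled over four molecular compositions, PE and PS from
# the 16:0_18:1 composition.
PC:
  c1: 0.40
  c2: 1.91
  n_points: 7
  source: published PC calibration
PE:
  c1: 0.38
  c2: 1.66
  n_points: 7
  source: published PE calibration
PS:
  c1: 0.72
  c2: 1.33
  n_points: 7
  source: published PS calibration
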