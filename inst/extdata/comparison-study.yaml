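# Walking-aperture comparison study on the 5C1 geometry: the configuration
# used by `replicate_comparison()`, expressed in the CLI config format
# (see ?read_config). Units are carried in the key names.
probe:
  preset: 5c1
pulse:
  center_frequency_mhz: 3.5
  fractional_bandwidth: 0.5
sequence:
  n_beams: 31          # clinical sequence uses 121 over the same span
  span_deg: 72.206     # beam axes from -36.103 to +36.103 degrees
  focal_depth_mm: 97
  subaperture: 96
medium:
  c_m_s: 1540
grid:
  n_theta: 512
  dr_mm: 0.44
  max_depth_mm: 128
  margin_rad: 0.155
recon:
  f_number: 2
  band_mode: taper
  band_taper: 0.25
seed: 1
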