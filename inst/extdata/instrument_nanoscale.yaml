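# Synthetic nanoscale instrument profile (units: nm, degrees, uL, uL/min)
name: nanoscale
optics:
  wavelength: 405
  medium_ri: 1.343
  aperture_center: 90
  half_angle: 60
  n_polar: 24
  n_azimuth: 24
scatter_gain_log10: 2.5
scatter_cv: 0.05
electronic_noise_sd: 20
trigger_threshold: 150
trigger_channel: VSSC_H
flow_rate: 1
acquired_volume: 2
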