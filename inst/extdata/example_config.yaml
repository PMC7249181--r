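# Example run configuration for a Mediterranean hedgerow-olive RDI campaign.
seed: 1
scenario:
  year: 2016
  latitude: 38.82
  elevation: 185
  annual_rainfall: 503.56
  wet_season_rain_fraction: 0.8
calendar:
  phase_1_start: 2016-03-01
  phase_2_start: 2016-07-01
  phase_3_start: 2016-09-15
  season_end: 2016-10-31
thresholds:
  phase_1: -1.4
  phase_2: -2.0
  phase_3: -1.6
envelope_pct: 0.2
feedback_gain: 0.3
comfort_zone:
  lower: 0.4
  upper: 0.8
emitter:
  emitter_discharge: 1.6
  emitter_spacing: 0.67
  row_spacing: 4
soil: {}
field:
  n_rows: 30
  n_cols: 31
  cell_size: 10
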