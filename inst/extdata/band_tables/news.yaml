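# National Early Warning Score (2012 release).
# Intervals are half-open [lo,hi); integer vitals fall on band edges as charted.
score_name: NEWS
source_version: "rcp-2012"
components:
  respiratory_rate:
    type: numeric
    unit: breaths/min
    range: [0, .inf]
    bands:
      - {interval: "[0,9)",   points: 3}
      - {interval: "[9,12)",  points: 1}
      - {interval: "[12,21)", points: 0}
      - {interval: "[21,25)", points: 2}
      - {interval: "[25,inf)", points: 3}
  spo2:
    type: numeric
    unit: percent
    range: [0, 101]
    bands:
      - {interval: "[0,92)",   points: 3}
      - {interval: "[92,94)",  points: 2}
      - {interval: "[94,96)",  points: 1}
      - {interval: "[96,101)", points: 0}
  supplemental_o2:
    type: boolean
    points: {"TRUE": 2, "FALSE": 0}
  temperature:
    type: numeric
    unit: degC
    range: [0, .inf]
    bands:
      - {interval: "[0,35.1)",    points: 3}
      - {interval: "[35.1,36.1)", points: 1}
      - {interval: "[36.1,38.1)", points: 0}
      - {interval: "[38.1,39.1)", points: 1}
      - {interval: "[39.1,inf)",  points: 2}
  systolic_bp:
    type: numeric
    unit: mm Hg
    range: [0, .inf]
    bands:
      - {interval: "[0,91)",    points: 3}
      - {interval: "[91,101)",  points: 2}
      - {interval: "[101,111)", points: 1}
      - {interval: "[111,220)", points: 0}
      - {interval: "[220,inf)", points: 3}
  heart_rate:
    type: numeric
    unit: beats/min
    range: [0, .inf]
    bands:
      - {interval: "[0,41)",    points: 3}
      - {interval: "[41,51)",   points: 1}
      - {interval: "[51,91)",   points: 0}
      - {interval: "[91,111)",  points: 1}
      - {interval: "[111,131)", points: 2}
      - {interval: "[131,inf)", points: 3}
  consciousness:
    type: categorical
    # AVPU; any non-alert level scores 3 (new confusion folded into non-alert)
    points: {A: 0, C: 3, V: 3, P: 3, U: 3}
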