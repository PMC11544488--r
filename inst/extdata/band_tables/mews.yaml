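# Modified Early Warning Score, 5-component ward variant (no urine output).
# Intervals are half-open [lo,hi) on the native unit of each vital.
score_name: MEWS
source_version: "subbe-2001-5component"
components:
  systolic_bp:
    type: numeric
    unit: mm Hg
    range: [0, .inf]
    bands:
      - {interval: "[0,71)",    points: 3}
      - {interval: "[71,81)",   points: 2}
      - {interval: "[81,101)",  points: 1}
      - {interval: "[101,200)", points: 0}
      - {interval: "[200,inf)", points: 2}
  heart_rate:
    type: numeric
    unit: beats/min
    range: [0, .inf]
    bands:
      - {interval: "[0,41)",    points: 2}
      - {interval: "[41,51)",   points: 1}
      - {interval: "[51,101)",  points: 0}
      - {interval: "[101,111)", points: 1}
      - {interval: "[111,130)", points: 2}
      - {interval: "[130,inf)", points: 3}
  respiratory_rate:
    type: numeric
    unit: breaths/min
    range: [0, .inf]
    bands:
      - {interval: "[0,9)",   points: 2}
      - {interval: "[9,15)",  points: 0}
      - {interval: "[15,21)", points: 1}
      - {interval: "[21,30)", points: 2}
      - {interval: "[30,inf)", points: 3}
  temperature:
    type: numeric
    unit: degC
    range: [0, .inf]
    bands:
      - {interval: "[0,35)",     points: 2}
      - {interval: "[35,38.5)",  points: 0}
      - {interval: "[38.5,inf)", points: 2}
  consciousness:
    type: categorical
    # AVPU; new confusion (C) treated as a voice-level disturbance
    points: {A: 0, C: 1, V: 1, P: 2, U: 3}
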