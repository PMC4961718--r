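{
  "variables": {
    "hs": {
      "orientation": "higher",
      "attempts": 1
    },
    "ff": {
      "orientation": "lower",
      "attempts": 1
    },
    "dribbling": {
      "orientation": "lower",
      "attempts": 2
    },
    "ball_control": {
      "orientation": "lower",
      "attempts": 2
    },
    "juggling": {
      "orientation": "higher",
      "attempts": 2
    },
    "sprint_40m": {
      "orientation": "lower",
      "attempts": 2
    },
    "yoyo_ir1": {
      "orientation": "higher",
      "attempts": 1
    },
    "cmj": {
      "orientation": "higher",
      "attempts": 2
    },
    "pct_adult_height": {
      "orientation": "higher",
      "attempts": 1
    }
  },
  "missing_token": "NA"
}
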