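{
  "leaves": {
    "Lying": "Sedentary",
    "SittingNotInTransport": "Sedentary",
    "SittingInTransport": "Sedentary",
    "Standing": "Upright",
    "LowStepping": "Upright",
    "ModerateStepping": "Upright",
    "VigorousStepping": "Upright",
    "Cycling": "Cycling"
  },
  "thigh": {
    "sitting": ["SittingNotInTransport"],
    "sitting-in-transport": ["SittingInTransport"],
    "cycling": ["Cycling"],
    "upright": ["Standing", "LowStepping", "ModerateStepping", "VigorousStepping"],
    "stepping": ["LowStepping", "ModerateStepping", "VigorousStepping"],
    "lying-primary": ["Lying"],
    "lying-secondary": ["Lying"],
    "sedentary": ["Lying", "SittingNotInTransport", "SittingInTransport"]
  },
  "api": {
    "STILL": ["Lying", "SittingNotInTransport", "Standing"],
    "IN_VEHICLE": ["SittingInTransport"],
    "ON_FOOT": ["LowStepping", "ModerateStepping", "VigorousStepping"],
    "WALKING": ["LowStepping", "ModerateStepping"],
    "RUNNING": ["VigorousStepping"],
    "ON_BICYCLE": ["Cycling"],
    "TILTING": [],
    "UNKNOWN": []
  },
  "met_categories": {
    "light_max": 2.99,
    "moderate_min": 3.0,
    "moderate_max": 5.99,
    "vigorous_min": 6.0,
    "vigorous_max": 8.99,
    "vigorous_line": 6.0
  }
}
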