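{
  "comment": "Bottom-modulation quadratics Bottom(x) = a x^2 + b x + c (x = itraconazole tissue concentration, ug/mL), dose regimens, and averaging exclusion rules.",
  "bottom_modulation": {
    "gemcitabine":  {"a": 2.44, "b": -1.95, "c": -1.06},
    "fluorouracil": {"a": 2.15, "b": -1.15, "c": -0.47}
  },
  "itraconazole_molecular_weight": 705.64,
  "calibration_micromolar": [0, 4, 6],
  "regimens": {
    "gemcitabine":      {"route": "infusion", "rate": 15.7, "duration": 120},
    "fluorouracil":     {"route": "bolus", "dose": 900},
    "itraconazole_100": {"route": "infusion", "dose": 100, "duration": 60},
    "itraconazole_300": {"route": "infusion", "dose": 300, "duration": 60},
    "itraconazole_500": {"route": "infusion", "dose": 500, "duration": 60},
    "rounded_rates":    {"itraconazole_100": 1.7, "itraconazole_300": 5, "itraconazole_500": 8.3}
  },
  "averaging_exclusions": {
    "gemcitabine":  {"bottom": ["I2"], "steepness": ["I0"]},
    "fluorouracil": {"bottom": ["I2"]}
  }
}
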