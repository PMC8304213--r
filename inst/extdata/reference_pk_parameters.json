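{
  "comment": "Two-compartment PK parameter sets fitted from literature human plasma concentration-time profiles (units: mL, mL/min, 1/min).",
  "gemcitabine":  {"Vd1": 68019.62, "Vd2": 444.79,   "CL": 3771.20, "k12": 6.64e-4, "k21": 0.102},
  "fluorouracil": {"Vd1": 9265.14,  "Vd2": 2791.84,  "CL": 850.01,  "k12": 3.21e-2, "k21": 0.107},
  "itraconazole": {"Vd1": 8145.37,  "Vd2": 82776.88, "CL": 228.45,  "k12": 2.38e-2, "k21": 2.34e-3}
}
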