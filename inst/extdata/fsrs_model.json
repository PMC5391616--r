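{
  "name": "fsrs-revised-profile",
  "version": "1.0 (transcribed coefficients; representative centring values and baseline survivals -- substitute a validated file for clinical use)",
  "horizon_years": 10,
  "male": {
    "coefficients": {
      "age": 0.0505,
      "sbp": 0.0140,
      "htn_med_eff": 0.3263,
      "diabetes": 0.3399,
      "smoker": 0.5202,
      "cvd": 0.5313,
      "af": 0.6107,
      "lvh": 0.7954
    },
    "center": {
      "age": 65,
      "sbp": 132,
      "htn_med_eff": 0.18,
      "diabetes": 0.08,
      "smoker": 0.30,
      "cvd": 0.12,
      "af": 0.02,
      "lvh": 0.04
    },
    "baseline_survival": 0.945
  },
  "female": {
    "coefficients": {
      "age": 0.0665,
      "sbp": 0.0056,
      "htn_med_eff": 0.4466,
      "diabetes": 0.5419,
      "smoker": 0.4163,
      "cvd": 0.1305,
      "af": 1.1773,
      "lvh": 0.8157
    },
    "center": {
      "age": 65,
      "sbp": 130,
      "htn_med_eff": 0.20,
      "diabetes": 0.07,
      "smoker": 0.28,
      "cvd": 0.08,
      "af": 0.02,
      "lvh": 0.03
    },
    "baseline_survival": 0.957
  }
}
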