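[
  {
    "name": "ethnicity_aa",
    "kind": "binary",
    "rr": 1.8,
    "reference": 0.11,
    "column": "ethnicity_aa"
  },
  {
    "name": "exercise",
    "kind": "categorical",
    "levels": ["low", "moderate", "high"],
    "rr": [1.0, 0.8, 0.7],
    "reference": [0.35, 0.40, 0.25]
  },
  {
    "name": "bmi",
    "kind": "continuous",
    "breaks": [25, 30, 35],
    "rr": [0.87, 1.0, 1.15, 1.34],
    "reference": [0.32, 0.38, 0.19, 0.11]
  },
  {
    "name": "waist",
    "kind": "continuous",
    "breaks": [88, 102],
    "rr": [0.84, 1.0, 1.20],
    "reference": [0.30, 0.40, 0.30]
  },
  {
    "name": "height",
    "kind": "continuous",
    "breaks": [160, 170, 180],
    "rr": [1.08, 1.0, 0.92, 0.85],
    "reference": [0.25, 0.35, 0.30, 0.10]
  },
  {
    "name": "hdl",
    "kind": "continuous",
    "breaks": [40, 50, 60],
    "rr": [1.13, 1.0, 0.89, 0.79],
    "reference": [0.22, 0.30, 0.27, 0.21]
  },
  {
    "name": "hrt",
    "kind": "binary",
    "rr": 0.8,
    "reference": 0.25,
    "column": "hrt",
    "applies": "postmenopausal_female"
  }
]
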