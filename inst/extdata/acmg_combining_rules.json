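{
  "description": "ACMG/AMP 2015 standard evidence-combining table. Each entry lists minimum counts per evidence-strength category (PVS very strong pathogenic, PS strong, PM moderate, PP supporting; BA stand-alone benign, BS strong, BP supporting).",
  "combinations": {
    "Pathogenic": [
      {"PVS": 1, "PS": 1},
      {"PVS": 1, "PM": 2},
      {"PVS": 1, "PM": 1, "PP": 1},
      {"PVS": 1, "PP": 2},
      {"PS": 2},
      {"PS": 1, "PM": 3},
      {"PS": 1, "PM": 2, "PP": 2},
      {"PS": 1, "PM": 1, "PP": 4}
    ],
    "Likely pathogenic": [
      {"PVS": 1, "PM": 1},
      {"PS": 1, "PM": 1},
      {"PS": 1, "PP": 2},
      {"PM": 3},
      {"PM": 2, "PP": 2},
      {"PM": 1, "PP": 4}
    ],
    "Benign": [
      {"BA": 1},
      {"BS": 2}
    ],
    "Likely benign": [
      {"BS": 1, "BP": 1},
      {"BP": 2}
    ]
  }
}
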