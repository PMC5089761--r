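{
  "groups": [
    {"group": "MS", "n_male": 8, "n_female": 70},
    {"group": "SIB", "n_male": 38, "n_female": 83},
    {"group": "HC", "n_male": 33, "n_female": 70}
  ]
}
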