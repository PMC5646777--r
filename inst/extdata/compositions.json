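[
  {
    "name": "pellets",
    "comment": "standard rodent pellets (Ssniff V2233)",
    "energy_mj_per_100g": 1.32,
    "fat_g_per_100g": 3.3,
    "pufa_g_per_100g": 1.97,
    "la_g_per_100g": 1.64,
    "ala_g_per_100g": 0.33
  },
  {
    "name": "seeds",
    "comment": "sunflower seeds; PUFA almost entirely LA, <0.1 g/100 g other PUFAs",
    "energy_mj_per_100g": 2.45,
    "fat_g_per_100g": 51.5,
    "pufa_g_per_100g": 23.14,
    "la_g_per_100g": 23.05,
    "ala_g_per_100g": 0.0
  }
]
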