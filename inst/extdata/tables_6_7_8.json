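[
  {"probe": "grain_4um", "species": "H-1", "kB_ug_per_mev_cm2": 300, "kB_stderr": 20, "rl0": 1.13, "let_min_mev_cm": 3, "let_max_mev_cm": 45},
  {"probe": "grain_38um", "species": "H-1", "kB_ug_per_mev_cm2": 300, "kB_stderr": 30, "rl0": 1.09, "let_min_mev_cm": 3, "let_max_mev_cm": 45},
  {"probe": "single_crystal", "species": "H-1", "kB_ug_per_mev_cm2": 250, "kB_stderr": 30, "rl0": 0.856, "let_min_mev_cm": 3, "let_max_mev_cm": 45},
  {"probe": "grain_4um", "species": "He-4", "kB_ug_per_mev_cm2": 120, "kB_stderr": 30, "rl0": 1.3, "let_min_mev_cm": 20, "let_max_mev_cm": 240},
  {"probe": "grain_38um", "species": "He-4", "kB_ug_per_mev_cm2": 110, "kB_stderr": 35, "rl0": 1.2, "let_min_mev_cm": 20, "let_max_mev_cm": 240},
  {"probe": "single_crystal", "species": "He-4", "kB_ug_per_mev_cm2": 100, "kB_stderr": 42, "rl0": 0.78, "let_min_mev_cm": 20, "let_max_mev_cm": 240},
  {"probe": "grain_4um", "species": "C-12", "kB_ug_per_mev_cm2": 1.8, "kB_stderr": 0.2, "rl0": 0.2, "let_min_mev_cm": 90, "let_max_mev_cm": 1700},
  {"probe": "grain_38um", "species": "C-12", "kB_ug_per_mev_cm2": 1.7, "kB_stderr": 0.3, "rl0": 0.19, "let_min_mev_cm": 90, "let_max_mev_cm": 1700},
  {"probe": "single_crystal", "species": "C-12", "kB_ug_per_mev_cm2": 2.5, "kB_stderr": 0.4, "rl0": 0.06, "let_min_mev_cm": 90, "let_max_mev_cm": 1700}
]
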