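{
  "n_autosomal_markers": 150,
  "n_z_markers": 60,
  "n_w_markers": 10,
  "n_neo_w_markers": 10,
  "n_neo_z_markers": 40,
  "n_block_markers": 40,
  "group_sizes": [
    {"sex": "M", "population_class": "pure_inland",    "n": 18},
    {"sex": "M", "population_class": "hybrid_inland",  "n": 14},
    {"sex": "M", "population_class": "hybrid_coastal", "n": 14},
    {"sex": "M", "population_class": "pure_coastal",   "n": 28},
    {"sex": "F", "population_class": "pure_inland",    "n": 10},
    {"sex": "F", "population_class": "hybrid_inland",  "n": 6},
    {"sex": "F", "population_class": "hybrid_coastal", "n": 10},
    {"sex": "F", "population_class": "pure_coastal",   "n": 12}
  ],
  "seed": 20260926
}
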