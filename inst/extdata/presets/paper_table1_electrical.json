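{
  "name": "paper_table1_electrical",
  "geometry": {
    "dimension": 1,
    "bath_extent": 0.015,
    "gel_shape": "interval",
    "gel_extent": 0.0025,
    "gel_center": 0.0075,
    "refinement_band": 0.002,
    "base_resolution": 4e-4,
    "refined_resolution": 4e-5
  },
  "constants": {
    "faraday": 9.6487e4,
    "gas_constant": 8.3143,
    "temperature": 293,
    "vacuum_permittivity": 8.854e-12,
    "relative_permittivity": 100
  },
  "species": [
    {"name": "Na+", "valence": 1, "diffusivity": 1e-7},
    {"name": "Cl-", "valence": -1, "diffusivity": 1e-7}
  ],
  "fixed_charge": {"concentration": 2, "valence": -1, "region": "gel"},
  "bath": {"molarity": 1},
  "protocol": {"type": "electrical", "applied_mV": 50, "anode_side": "left"},
  "solver": {
    "order": 2,
    "dt": 8,
    "t_end": 1600,
    "steady_tolerance": 1e-8,
    "stop_at_steady": true
  },
  "output": {},
  "seed": 1
}
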