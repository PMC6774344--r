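{
  "name": "paper_table1_electrical_scaled",
  "geometry": {
    "dimension": 1,
    "bath_extent": 1.5e-6,
    "gel_shape": "interval",
    "gel_extent": 2.5e-7,
    "gel_center": 7.5e-7,
    "refinement_band": 2e-7,
    "base_resolution": 4e-8,
    "refined_resolution": 4e-9
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
    "dt": 4e-7,
    "t_end": 4e-5,
    "steady_tolerance": 100,
    "stop_at_steady": true
  },
  "output": {},
  "seed": 1
}
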