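{
  "comment": "Synthetic eight-macrostate kinetic network fixture for a two-domain binding protein. Populations (percent) are a synthetic transcription constrained by the published text: the three ligand-induced closed states S1+S1p+S4p sum to 24%, the ligand-induced open state S2 is 4%, and each large-domain-bound state (S4, S5, S6) is more populated than every small-domain-bound state (S1, S2, S3). Edge propensities encode the network topology: fast opening-closing within each binding-site cluster (S1-S2, S5-S6), slower transit through the semi-closed states (S3-S4 bridge), and slow off-pathway excursions S1-S1p and S4-S4p.",
  "macro_names": ["S1", "S2", "S3", "S4", "S5", "S6", "S1p", "S4p"],
  "populations_percent": [12, 4, 8, 18, 16, 30, 7, 5],
  "ligand_induced_closed": ["S1", "S1p", "S4p"],
  "n_micro_per_macro": 3,
  "intra_rate": 0.45,
  "lag_unit_ns": 30,
  "edges": [
    {"a": "S1", "b": "S2", "rate": 0.09},
    {"a": "S1", "b": "S3", "rate": 0.04},
    {"a": "S2", "b": "S3", "rate": 0.05},
    {"a": "S3", "b": "S4", "rate": 0.02},
    {"a": "S4", "b": "S5", "rate": 0.05},
    {"a": "S4", "b": "S6", "rate": 0.04},
    {"a": "S5", "b": "S6", "rate": 0.09},
    {"a": "S1", "b": "S1p", "rate": 0.012},
    {"a": "S4", "b": "S4p", "rate": 0.012}
  ]
}
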