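{
  "comment": "Four-state smFRET fixture. Emission means and stationary populations are the published values for states E1-E4 of ligand-bound GlnBP; the emission sd and the hidden-chain proposal rate are synthetic choices (the published work does not print a chain matrix): a Metropolis chain with uniform symmetric proposal 0.05 between all state pairs and the printed stationary populations gives mean dwell times near 0.7 s at 100 ms frames.",
  "state_names": ["E1", "E2", "E3", "E4"],
  "emission_means": [0.15, 0.31, 0.51, 0.68],
  "populations": [0.24, 0.23, 0.33, 0.20],
  "emission_sd": 0.06,
  "proposal_rate": 0.05,
  "frame_interval_s": 0.1
}
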