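{
  "dataset": "dihydropteridone-oxadiazole MCF-7 inhibitor study tables",
  "n_panel_compounds": 33,
  "n_modeling_compounds": 31,
  "n_train": 25,
  "n_test": 6,
  "n_candidates": 5,
  "n_excluded_from_modeling": 2,
  "excluded_note": "Two of the 33 panel compounds do not appear in the modeling table; their identity is not recorded in the source and is deliberately not guessed.",
  "numbering_note": "Modeling-table compound numbering does not align with the panel numbering (e.g. modeling row 12 carries the descriptors of panel compound 14); the two tables are kept as separate, unjoined fixtures.",
  "md5": {
    "table2_panel.csv": "9f8d9ca87d2fecb54759ff4d2560d5b2",
    "table3_modeling.csv": "f1abab55ef36581789f0afb6be878ce4",
    "table5_test_pairs.csv": "12838b7014ccf68e1401df4f4ff8ed74",
    "table7_candidates.csv": "256ad20619d0d55564919b1878088b3f",
    "table8_properties.csv": "2d2b2c582e27b6c62e0c61c72eddffbe"
  }
}
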