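{
  "_comment": "Pipeline configuration for `emligfit run --config <file>`. Paths are resolved relative to the working directory; explicit command-line flags override these values. `models` lists candidate PDB files; `resolution` (Angstrom) is required when the map header carries no nominal resolution; `reducer` is `final_frame` or `last20_mean`; `duration` is the flexible-fitting length in ps.",
  "models": ["candidate_1.pdb", "candidate_2.pdb", "candidate_3.pdb",
             "candidate_4.pdb", "candidate_5.pdb"],
  "map": "target_map.mrc",
  "ground_truth": "ground_truth.pdb",
  "out": "run_output",
  "resolution": 3.2,
  "duration": 50,
  "seed": 0,
  "reducer": "final_frame"
}
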