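{
  "seed": 1,
  "outdir": "pipeline_out",
  "atlas": {
    "n_genes": 1200,
    "n_cells_per_pathology": { "PN": 300, "AN": 300, "MPNST": 300 },
    "n_clusters": 6,
    "holdout_fraction": 0.2
  },
  "panel": {
    "n_proteins": 400,
    "n_signal": 40,
    "effect_size": 1.5
  }
}
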