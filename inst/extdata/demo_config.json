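{
  "seed": 42,
  "out_dir": "spirotax_demo",
  "stages": {
    "simulate": {
      "ancestor_length": 20000,
      "alignable_fraction": 0.3,
      "within_identity": 0.85,
      "n_segments": 6,
      "n_taxa": 32,
      "rho": 0.8,
      "groups": ["free_living", "host_associated"],
      "genomes_per_group": 4
    },
    "ggd": { "synthetic": true },
    "cogmap": { "synthetic": true, "transform": "arcsine_sqrt" },
    "contrasts": { "synthetic": true }
  }
}
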