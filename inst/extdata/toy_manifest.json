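{
  "n_metabolites": 73,
  "n_reactions": 86,
  "n_genes": 48,
  "n_exchanges": 20,
  "compartments": ["c", "e", "m"],
  "biomass_default_medium": 2.25,
  "atp_capacity_default_medium": 121.5,
  "nadph_capacity_default_medium": 129.999999999999,
  "lactate_capacity_default_medium": 21.6666666666665
}
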