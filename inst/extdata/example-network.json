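{
  "comment": "Default five-species scheme: 50 nM protein, 5 nM cognate sites, 0.5 mM lattice sites; constants on edges touching the secondary/cross-linked species are illustrative.",
  "totals": {"protein": 5e-8, "more": 5e-9, "ns": 5e-4},
  "transitions": [
    {"name": "specific dimer formation",
     "consumed": {"free_protein": 2, "more_free": 1},
     "produced": {"specific_dimer": 1},
     "k_ref": 1.189060642092747e15, "ref_na": 0.2, "dm": -6.8},
    {"name": "secondary (oversaturated) loading",
     "consumed": {"specific_dimer": 1, "free_protein": 1},
     "produced": {"secondary_complex": 1},
     "k_ref": 3e4, "ref_na": 0.2, "dm": 0},
    {"name": "nonspecific site binding",
     "consumed": {"free_protein": 1, "ns_free": 1},
     "produced": {"nonspecific_complex": 1},
     "k_ref": 4e3, "ref_na": 0.2, "dm": -9},
    {"name": "intersegmental bridge formation",
     "consumed": {"specific_dimer": 1, "nonspecific_complex": 1},
     "produced": {"crosslinked_intermediate": 1},
     "k_ref": 1e9, "ref_na": 0.2, "dm": 0},
    {"name": "lattice-site release (ion uptake)",
     "consumed": {"crosslinked_intermediate": 1},
     "produced": {"secondary_complex": 1, "ns_free": 1},
     "k_ref": 7.5e-9, "ref_na": 0.2, "dm": 9}
  ]
}
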