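{
  "comment": "Residue property registry. code: sequence token; chirality: L|D|achiral; side_chain_charge: formal side-chain charge at pH 7.4; polarity_class: apolar|acidic|basic|polar_uncharged; hydrophobicity: Eisenberg consensus scale (non-naturals mapped to nearest natural analog); helix_propensity_class: high|low; is_staple_residue: arm of a covalent crosslink. D-enantiomer entries (dX) are derived at load time from the parent L entry.",
  "residues": [
    {"code": "A", "chirality": "L", "side_chain_charge": 0,  "polarity_class": "apolar",          "hydrophobicity": 0.62,  "helix_propensity_class": "high", "is_staple_residue": false},
    {"code": "R", "chirality": "L", "side_chain_charge": 1,  "polarity_class": "basic",           "hydrophobicity": -2.53, "helix_propensity_class": "high", "is_staple_residue": false},
    {"code": "N", "chirality": "L", "side_chain_charge": 0,  "polarity_class": "polar_uncharged", "hydrophobicity": -0.78, "helix_propensity_class": "high", "is_staple_residue": false},
    {"code": "D", "chirality": "L", "side_chain_charge": -1, "polarity_class": "acidic",          "hydrophobicity": -0.90, "helix_propensity_class": "high", "is_staple_residue": false},
    {"code": "C", "chirality": "L", "side_chain_charge": 0,  "polarity_class": "polar_uncharged", "hydrophobicity": 0.29,  "helix_propensity_class": "high", "is_staple_residue": false},
    {"code": "Q", "chirality": "L", "side_chain_charge": 0,  "polarity_class": "polar_uncharged", "hydrophobicity": -0.85, "helix_propensity_class": "high", "is_staple_residue": false},
    {"code": "E", "chirality": "L", "side_chain_charge": -1, "polarity_class": "acidic",          "hydrophobicity": -0.74, "helix_propensity_class": "high", "is_staple_residue": false},
    {"code": "G", "chirality": "achiral", "side_chain_charge": 0, "polarity_class": "apolar",     "hydrophobicity": 0.48,  "helix_propensity_class": "low",  "is_staple_residue": false},
    {"code": "H", "chirality": "L", "side_chain_charge": 0,  "polarity_class": "basic",           "hydrophobicity": -0.40, "helix_propensity_class": "high", "is_staple_residue": false},
    {"code": "I", "chirality": "L", "side_chain_charge": 0,  "polarity_class": "apolar",          "hydrophobicity": 1.38,  "helix_propensity_class": "high", "is_staple_residue": false},
    {"code": "L", "chirality": "L", "side_chain_charge": 0,  "polarity_class": "apolar",          "hydrophobicity": 1.06,  "helix_propensity_class": "high", "is_staple_residue": false},
    {"code": "K", "chirality": "L", "side_chain_charge": 1,  "polarity_class": "basic",           "hydrophobicity": -1.50, "helix_propensity_class": "high", "is_staple_residue": false},
    {"code": "M", "chirality": "L", "side_chain_charge": 0,  "polarity_class": "apolar",          "hydrophobicity": 0.64,  "helix_propensity_class": "high", "is_staple_residue": false},
    {"code": "F", "chirality": "L", "side_chain_charge": 0,  "polarity_class": "apolar",          "hydrophobicity": 1.19,  "helix_propensity_class": "high", "is_staple_residue": false},
    {"code": "P", "chirality": "L", "side_chain_charge": 0,  "polarity_class": "apolar",          "hydrophobicity": 0.12,  "helix_propensity_class": "low",  "is_staple_residue": false},
    {"code": "S", "chirality": "L", "side_chain_charge": 0,  "polarity_class": "polar_uncharged", "hydrophobicity": -0.18, "helix_propensity_class": "high", "is_staple_residue": false},
    {"code": "T", "chirality": "L", "side_chain_charge": 0,  "polarity_class": "polar_uncharged", "hydrophobicity": -0.05, "helix_propensity_class": "high", "is_staple_residue": false},
    {"code": "W", "chirality": "L", "side_chain_charge": 0,  "polarity_class": "apolar",          "hydrophobicity": 0.81,  "helix_propensity_class": "high", "is_staple_residue": false},
    {"code": "Y", "chirality": "L", "side_chain_charge": 0,  "polarity_class": "polar_uncharged", "hydrophobicity": 0.26,  "helix_propensity_class": "high", "is_staple_residue": false},
    {"code": "V", "chirality": "L", "side_chain_charge": 0,  "polarity_class": "apolar",          "hydrophobicity": 1.08,  "helix_propensity_class": "high", "is_staple_residue": false},
    {"code": "R8",  "chirality": "achiral", "side_chain_charge": 0, "polarity_class": "apolar",   "hydrophobicity": 1.06,  "helix_propensity_class": "high", "is_staple_residue": true},
    {"code": "S5",  "chirality": "achiral", "side_chain_charge": 0, "polarity_class": "apolar",   "hydrophobicity": 1.06,  "helix_propensity_class": "high", "is_staple_residue": true},
    {"code": "X",   "chirality": "achiral", "side_chain_charge": 0, "polarity_class": "apolar",   "hydrophobicity": 1.06,  "helix_propensity_class": "high", "is_staple_residue": true},
    {"code": "Cba", "chirality": "L", "side_chain_charge": 0,  "polarity_class": "apolar",        "hydrophobicity": 1.06,  "helix_propensity_class": "high", "is_staple_residue": false},
    {"code": "Aib", "chirality": "achiral", "side_chain_charge": 0, "polarity_class": "apolar",   "hydrophobicity": 0.62,  "helix_propensity_class": "high", "is_staple_residue": false},
    {"code": "Sar", "chirality": "achiral", "side_chain_charge": 0, "polarity_class": "apolar",   "hydrophobicity": 0.48,  "helix_propensity_class": "low",  "is_staple_residue": false},
    {"code": "Gla", "chirality": "L", "side_chain_charge": -2, "polarity_class": "acidic",        "hydrophobicity": -0.74, "helix_propensity_class": "high", "is_staple_residue": false},
    {"code": "aMeE","chirality": "L", "side_chain_charge": -1, "polarity_class": "acidic",        "hydrophobicity": -0.74, "helix_propensity_class": "high", "is_staple_residue": false},
    {"code": "aMeF","chirality": "L", "side_chain_charge": 0,  "polarity_class": "apolar",        "hydrophobicity": 1.19,  "helix_propensity_class": "high", "is_staple_residue": false},
    {"code": "hS",  "chirality": "L", "side_chain_charge": 0,  "polarity_class": "polar_uncharged","hydrophobicity": -0.18, "helix_propensity_class": "high", "is_staple_residue": false},
    {"code": "hR",  "chirality": "L", "side_chain_charge": 1,  "polarity_class": "basic",         "hydrophobicity": -2.53, "helix_propensity_class": "high", "is_staple_residue": false},
    {"code": "KN3", "chirality": "L", "side_chain_charge": 0,  "polarity_class": "polar_uncharged","hydrophobicity": -1.50, "helix_propensity_class": "high", "is_staple_residue": false},
    {"code": "bA",  "chirality": "achiral", "side_chain_charge": 0, "polarity_class": "apolar",   "hydrophobicity": 0.62,  "helix_propensity_class": "high", "is_staple_residue": false}
  ]
}
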