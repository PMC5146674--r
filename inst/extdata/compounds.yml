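# Compound registry: anion formulas, formal charges, and standard
# formation free energies at pH 7 (kJ/mol, Thauer convention).
propionate: {formula: C3H5O2, charge: -1, dGf: -361.08, phase: aqueous}
acetate:    {formula: C2H3O2, charge: -1, dGf: -369.41, phase: aqueous}
formate:    {formula: CHO2,   charge: -1, dGf: -351.04, phase: aqueous}
H2:         {formula: H2,     charge: 0,  dGf: 0.0,     phase: gas}
CH4:        {formula: CH4,    charge: 0,  dGf: -50.75,  phase: gas}
CO2:        {formula: CO2,    charge: 0,  dGf: -394.36, phase: gas}
HCO3:       {formula: CHO3,   charge: -1, dGf: -586.85, phase: aqueous}
H2O:        {formula: H2O,    charge: 0,  dGf: -237.18, phase: aqueous}
H+:         {formula: H,      charge: 1,  dGf: -39.87,  phase: aqueous}
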