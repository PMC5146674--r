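# mecflux

Electron-flux accounting, performance metrics and bioenergetics for
microbial electrolysis cells (MECs) fed with fermentable substrates.

## The problem

In an MEC, microbes oxidize an organic electron donor at the anode and
the liberated electrons evolve hydrogen at the cathode. When the donor
is fermentable — propionate is the canonical case — the electrons do
not all become current: fermenters split the donor into acetate,
formate and H₂, and methanogens compete with exoelectrogens for those
intermediates. The set anode potential (SAP) decides how much energy an
exoelectrogen can gain, and therefore how the electrons split between
electrical current, methane and everything else (biomass, soluble
products — the "undefined" sinks).

`mecflux` gives researchers working with such reactors a tested toolkit
for the bookkeeping this involves:

* **Electron-equivalent stoichiometry.** Every compound's degree of
  reduction γ = 4C + H − 2O − 3N − z (electrons released by complete
  oxidation to HCO₃⁻/H₂O/NH₄⁺; γ = 14 for propionate, 8 for
  acetate and CH₄, 2 for H₂ and formate), with balanced oxidation
  half-reactions as an independent cross-check.
* **Performance metrics.** Volumetric current density I_V (A/m³),
  coulombic efficiency CE = 100·Q/(F·γ·n_donor), cathodic H₂ rate
  (m³ H₂/m³/day), H₂ yield (mol/mol) and substrate removal, from raw
  current traces, HPLC series and headspace gas measurements.
* **The electron ledger.** Donor electrons distributed over measured
  sinks — current (Q/F), CH₄ (8 e⁻/mol), H₂ (2 e⁻/mol), residual
  acids — with the remainder closing the balance as undefined sinks, so
  percentages always total exactly 100.
* **Anode-potential bioenergetics.** The energy gain of anode
  respiration, ΔG°′ = −nF(E_anode − E°′), evaluated against the free
  energies of the competing methanogenic reactions (Thauer pH-7
  formation energies) to rank current vs methane per donor and
  potential.
* **Community metrics.** Alpha diversity (observed OTUs, bias-corrected
  Chao1, Shannon, Gini–Simpson, Good's coverage), seeded rarefaction,
  three-way OTU sharing (Venn regions), Archaea:Bacteria ratios and
  rank-level abundance tables with minor taxa pooled into "others".
* **A synthetic-data generator.** Seeded fed-batch cycles with imposed
  electron-routing fractions and known ground truth, plus OTU tables
  with configurable dominance (Geobacter-like anode biofilms) and
  archaeal fractions — so the whole pipeline is testable end to end
  without any instrument data.

## Worked example

Simulate one 36 mM propionate cycle at 0 V vs SHE routing 71% of
electrons to current, 22.9% to methane, 0.03% to residual H₂ (the rest
undefined), with 2% measurement noise, then analyse it as if it were
real data:

```r
library(mecflux)
sim <- simulate_batch_cycle(sim_config(seed = 1))
performance_metrics(sim$record)
#> <performance_metrics>
#>   I_V         120.4 A/m^3
#>   CE           70.9 %
#>   Q_H2         0.92 m^3 H2/m^3/day
#>   Y_H2         4.61 mol H2/mol donor
#>   removal     100.0 % (8.0 mM/day)
electron_balance(sim$record)
#> <sink_balance> donor = 20.16 m e-eq
#>                 sink m_eeq percent
#>              current 14.29   70.89
#>              methane  4.71   23.34
#>             hydrogen  0.01    0.03
#>  residual_propionate  0.00    0.00
#>              acetate  0.00    0.00
#>              formate  0.00    0.00
#>            undefined  1.16    5.74
```

The fed donor carried 20.16 milli electron equivalents (36 mM × 40 mL
× 14 e⁻/mol); the ledger recovers the configured routing to within the
imposed measurement noise, and CE lands at 70.9% against the
configured 71%.

Why does methane win at negative potentials? Compare the two sinks
thermodynamically, per mol donor at standard biochemical conditions:

```r
favorability_matrix(c(-0.25, 0, 0.25), c("acetate", "H2"))
#>   e_anode_V   donor dG_current_kJ_mol dG_ch4_kJ_rxn dG_ch4_kJ_mol preferred
#> 1     -0.25 acetate             -21.6         -31.0         -31.0   methane
#> 2      0.00 acetate            -214.6         -31.0         -31.0   current
#> 3      0.25 acetate            -407.6         -31.0         -31.0   current
#> 4     -0.25      H2             -31.5        -135.6         -33.9   methane
#> 5      0.00      H2             -79.7        -135.6         -33.9   current
#> 6      0.25      H2            -127.9        -135.6         -33.9   current
```

At −0.25 V, acetoclastic methanogenesis (−31 kJ/mol) out-competes
anode respiration (−21.6 kJ/mol); at 0 V and above the anode offers
far more energy, so current dominates — mirroring the observed shift
of electron flux from methane toward current with rising potential.

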