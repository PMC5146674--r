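---
title: "Electron accounting and bioenergetics in propionate-fed MECs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Electron accounting and bioenergetics in propionate-fed MECs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mecflux)
```

## The accounting model

A microbial electrolysis cell fed a fermentable donor routes the
donor's electrons to several competing sinks. `mecflux` treats this as
strict double-entry bookkeeping in a single currency, the electron
equivalent: the degree of reduction of a CxHyOzNw compound with formal
charge z,

γ = 4C + H − 2O − 3N − z,

i.e. the moles of electrons released by complete oxidation to HCO₃⁻,
H₂O and NH₄⁺. The formula is the closed form of balancing the
oxidation half-reaction

donor + a H₂O → C HCO₃⁻ + N NH₄⁺ + h H⁺ + γ e⁻,

and the package computes both independently — the formula in
`electron_equivalents()`, the balance in `oxidation_half_reaction()` —
and asserts they agree for every compound. The −z term makes the anion
and free-acid conventions identical (propionate C₃H₅O₂⁻ and propionic
acid C₃H₆O₂ both give γ = 14), so it does not matter which form an
assay reports. Nitrogen is referenced to NH₄⁺ (−3 per N); no
nitrogenous donor appears in the shipped registry, but the formula and
balancer handle them (tested on alanine).

### The ledger

For one fed-batch cycle, `electron_balance()` expresses every measured
sink as a share of the fed donor's electron pool, γ_d · C₀ · V:

* electrical current: integrated charge / F (F = 96 485 C/mol e⁻),
* methane: 8 e⁻eq per mol (anode + cathode headspace combined, since
  the chambers exchange gas via the membrane and most studies pool
  them; configurable),
* hydrogen: 2 e⁻eq per mol, **anode headspace only** — cathodic H₂ is
  the product of the current already on the ledger and counting it
  again would double-book those electrons,
* residual donor, acetate, formate: final concentration × volume × γ.

The *undefined* entry (biomass, soluble microbial products, unmeasured
losses) is defined as the closure term, 100 − Σ(measured %), so the
ledger always totals exactly 100 by construction; a negative remainder
(over-closure, i.e. more electrons recovered than fed) is reported
with a warning rather than an error, because it is a real and
diagnostic failure mode of bench data. When the donor is fully
consumed — the usual endpoint, reported below detection limit — the
fed and consumed electron bases coincide.

Two companion operations express intermediate dynamics on the same
basis: `time_course_fractions()` converts an HPLC series to
percent-of-donor-electrons, 100·γ_i·C_i(t)/(γ_d·C_d,0), and
`pathway_fraction()` splits donor electrons over a fermentation
stoichiometry (propionate → acetate + 3 H₂ puts 8/14 = 57.1% of
electrons in acetate and 6/14 = 42.9% in H₂; a pathway summing above
100% is rejected as over-stoichiometric, below 100% flagged
incomplete).

## Performance metrics

`performance_metrics()` computes the standard figures of merit:

| metric | definition | units |
|---|---|---|
| I_V | peak smoothed current / anode liquid volume | A/m³ |
| CE | 100·Q/(F·γ_d·n_donor) | % |
| Q_H₂ | cathodic H₂ volume / (anode volume · days) | m³/m³/day |
| Y_H₂ | mol H₂ / mol donor (ceiling γ_d/2 = 7 for propionate) | mol/mol |
| removal | 100·(C₀−C_end)/C₀ and (C₀−C_end)/days | %, mM/day |

Numerical choices: charge is integrated with the trapezoid rule —
telemetry is piecewise-linear between samples, so the trapezoid is
exact for the recorded signal and a higher-order rule would only
pretend to more information; the peak current uses a moving-median
smooth (window 3) so a single telemetry spike cannot set I_V; all
volumetric quantities are normalized to the anode *liquid* volume
(40 mL in the default geometry), one consistent basis; gas amounts use
the ideal gas law at the measurement conditions (default 303.15 K,
1 atm — a 30 °C operating room) and can be re-expressed at a reporting
reference. CE above 100% warns instead of erroring, again because it
is diagnostic. Units are encoded in every field name (`_mM`, `_m3`,
`time_s`, `rate_mM_day`) to keep second-per-day slips out of user
code.

## Anode-potential bioenergetics

The energy available to a microbe respiring on the anode is

ΔG°′ = −nF(E_anode − E°′),

per mol donor at standard biological conditions (pH 7, 25 °C, 1 M /
1 atm), with E°′ the donor couple's standard biological potential.
`anode_energy_gain()` evaluates this, and `reaction_deltaG()` evaluates
full reactions from the packaged Thauer-convention formation energies
(HCO₃⁻ −586.85, H₂O −237.18, CH₄ −50.75, H⁺ −39.87, acetate −369.41,
formate −351.04, propionate −361.08 kJ/mol), verifying element and
charge balance before summing.

Two donor-couple profiles ship. The `"paper"` profile (acetate
−0.278 V, H₂ −0.413 V, formate −0.489 V vs SHE) is back-derived from a
published grid of anode energy gains so the package reproduces that
grid to one decimal; the `"literature"` profile carries textbook values
(−0.290, −0.414, −0.432 V). The formate discrepancy is the largest and
is deliberately left visible rather than silently averaged: users pick
the profile, the default favouring reproducibility of the published
grid. Outputs are rounded to one decimal kJ/mol, matching the precision
such grids are printed at.

`favorability_matrix()` ranks current against methanogenesis per
(potential, donor) pair. Because the methanogenic reference reactions
consume different donor amounts (4 H₂ per CH₄, 1 acetate per CH₄), the
ranking divides each reaction ΔG°′ by its donor coefficient and
compares kJ *per mol donor* — a common basis — while also reporting the
per-reaction value as conventionally printed. Ties are reported as
ties. Standard conditions only: a reaction-quotient helper
(`deltaG_with_quotient()`) is provided but the ranking does not apply
it, since in-situ activities are rarely known.

```{r thermo}
favorability_matrix(c(-0.25, 0, 0.25), "acetate")
```

## Community metrics

`alpha_diversity()` implements the formula-level indices directly:
observed OTUs; bias-corrected Chao1, S_obs + F₁(F₁−1)/(2(F₂+1)),
chosen over the classic F₁²/(2F₂) because it is finite when a sample
has no doubletons (the classic form is available by flag); Shannon
H = −Σ p log_b p with base 2 by default (base e selectable — published
index ranges in this field rarely state the base, and for
thousand-OTU samples both are plausible readings, so the choice is
explicit rather than buried); Gini–Simpson D = 1 − Σp², the
"probability two reads differ" form consistent with diverse anaerobic
communities scoring 0.7–0.9; and Good's coverage 100·(1 − F₁/N).
`rarefy_counts()` subsamples without replacement (multivariate
hypergeometric) to an even depth, seeded, dropping too-shallow samples
with a warning. `venn3()` does exact set algebra over three OTU sets;
`domain_ratio()` and `abundance_table()` work from semicolon-separated
lineages, the latter pooling taxa under 1% of total reads (threshold
configurable) into "others" and sorting rows lexicographically for
deterministic output.

## What the simulator emulates — and what it does not

`simulate_batch_cycle()` generates one fed-batch cycle under the
default study conditions: 40 mL anode, 36 mM propionate, zero-order
removal at 10.5 mM/day handing over to a continuity-matched
first-order tail below 2 mM (so the concentration profile is
near-linear for ~78 h and the current declines smoothly to ~0 at cycle
end, as fed-batch traces do), a 4.5-day cycle at 600 s telemetry.
Consumed electrons are routed instantaneously in configured fractions
— defaults 71 / 22.9 / 0.03 / 6.07 percent to current, CH₄, residual
H₂ and undefined, a realistic 0 V-like condition — giving
I(t) = f_current·γ_d·F·V·(−dC/dt), CH₄ at 1 mol per 8 e⁻eq, residual
H₂ at 1 mol per 2 e⁻eq, and cathodic H₂ by Faraday's law at 90%
recovery. Measurement noise is multiplicative Gaussian truncated at
zero (instrument CVs scale with signal), default CV 2% on current,
concentrations and gas volumes, applied to observables only; the exact
pre-noise routing is stored as ground truth and conservation is
asserted inside the generator. Concentrations below 0.05 mM are
censored to zero, as an HPLC would report them. The record's
accumulated charge carries coulomb-counter semantics (the exact
integral, as a potentiostat accumulates it) rather than a trapezoid of
the 10-min telemetry; the telemetry still integrates to the routed
charge within 0.5% and that bound is tested separately.

An "oc" scenario adds a triangular acetate pulse (default peak
9.9 mM near donor depletion) emulating open-circuit behaviour where
acetate transiently accumulates.

`simulate_otu_table()` draws reads multinomially from log-normal
expected abundances, with optional dominant-taxon weight (anode-like,
Geobacter at 0.45–0.65) and archaeal community fraction
(suspension-like, methanogen lineages).

What this does *not* model — and therefore what passing tests do and
do not show: routing fractions are imposed, not emergent from Monod
kinetics or microbial competition, so recovering them demonstrates
that the *measurement-to-ledger* pipeline is faithful, not that any
biological prediction is correct; there is no dissolved-gas (Henry's
law) partitioning, no crossover through the membrane (real crossover
is typically <0.5% and a config flag can subtract an estimate), no pH
drift, and OTU tables have no phylogenetic structure. Absolute
experimental values (a particular reactor's 103 A/m³ or 0.55 m³
H₂/m³/day) derive from physical measurements and are not reproduced —
the package reproduces their *definitions* and relative arithmetic.

## Problem sizes and determinism

The test suite runs the generator at its default resolution (≈650
telemetry samples per cycle), uses 20 seeded noisy cycles for the
fraction-recovery check (mean absolute error ≤ 2 percentage points at
CV 2%), 1 000 seeded draws for the rarefaction-expectation check, and
random 30-taxon tables against brute-force oracles at 1e−9 — sizes at
which every property is sharp while the whole suite runs in seconds.
All randomness flows through explicit integer seeds; identical seeds
give byte-identical simulations, and report files are written with
sorted keys so runs are diffable.

## Known limitations

* The γ formula covers C/H/O/N organics only — no S or P chemistry.
* Thermodynamics are standard-condition (the quotient helper exists
  but no activity corrections, temperature dependence, or
  electrode-kinetic losses).
* The ledger attributes all integrated charge to donor oxidation;
  capacitive currents are assumed negligible at fed-batch timescales.
* Alpha-diversity variants differ across sequencing pipelines; the
  package fixes one explicit set of formulas rather than reproducing
  any particular pipeline's output.
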