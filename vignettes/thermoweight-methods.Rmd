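---
title: "Completing and weighting a metabolic network by free energy"
author: "thermoweight"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Completing and weighting a metabolic network by free energy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermoweight)
```

## The problem

Group-contribution methods estimate standard Gibbs formation energies
($\Delta G_f$) of metabolites and standard reaction energies
($\Delta G^{\circ\prime}_r$) from molecular substructures, but leave gaps:
compounds containing substructures outside the method's scope (metal
complexes, pseudoatoms such as "R" groups) get no formation energy, and a
reaction energy cannot be computed directly when a participating compound's
formation energy is missing — unless the offending substructure cancels
between the two sides. In a genome-scale *E. coli* reconstruction this
leaves on the order of 16% of compounds and 4% of reactions without
energies, which blocks any downstream energetic analysis.

`thermoweight` closes those gaps with the model's own stoichiometry, then
uses the completed energies to (i) weight every reaction by its free-energy
dissipation rate and (ii) decompose the cell's steady-state free-energy
budget into environmental input, chemical dissipation and a physical
remainder.

## The completion model

Reaction energies are stoichiometry-weighted sums of per-species formation
energies,
$$\Delta G_{r} \;=\; \sum_i s_i\, \Delta G_{f,i},$$
with $s_i$ the signed stoichiometric coefficient. Writing $P$ for the
per-species formation-energy vector with zeros at unknown entries, $T$ for
the binary species $\times$ unknown-compound *transfer matrix* (a compound
has one formation energy shared by all its compartmental species), and $F$
for the reaction-energy vector, the model is
$$S^\top (P + T X) = F,$$
where $X$ collects the unknown compound energies. Rows with known $F$ whose
coefficient row of $S^\top T$ is nonzero constrain $X$; the reduced system
$QX = b$, $b = F - S^\top P$, is generally inconsistent and is solved in
the least-squares sense. The solution $X_0$ is back-substituted,
$F_0 = S^\top (P + T X_0)$, to fill the unknown reaction energies. Known
input energies are never overwritten; the consistency report compares them
with $F_0$ instead, in four categories (unknown energy; known energy
touching unknown compounds — the constraint rows; known energy touching
none; all known).

A subtlety worth naming: a compound moved *unchanged* between compartments
(a transport reaction) contributes canceling $\pm s$ coefficients to one
column of $S^\top T$, so such a reaction does **not** constrain the
compound even though the compound appears in it. The same cancellation is
why a reaction energy can be known while a participant's formation energy
is not.

### Numerical choices

* The solve is SVD-based with a relative singular-value cutoff of
  $10^{-10}\,\sigma_1$ (tunable). On rank deficiency the minimum-norm
  solution is returned and every unknown with a non-negligible null-space
  component is flagged *weakly determined* rather than silenced: those
  values are not unique and the flag travels into the output table.
* The rank of $Q$ is always reported, never assumed: whether the reduced
  system determines all unknowns is a property of the data set.
* Inference runs on the standard scale ($\Delta G^{\circ\prime}$); the
  concentration adjustment is applied afterwards, matching the order in
  which group-contribution tables are produced.

## Millimolar adjustment

Standard energies reference 1 M concentrations; cellular metabolites sit
near 1 mM. The adjusted energy is
$$\Delta G^{m}_r = \Delta G^{\circ\prime}_r
  + RT \sum_{i \in PR} n_i \ln c_i,$$
with $R = 1.987\times10^{-3}$ kcal mol$^{-1}$ K$^{-1}$, $T = 298$ K,
$c_i = 10^{-3}$ mol/L by default, dissolved H$_2$ and O$_2$ at their
saturation concentrations ($3.4\times10^{-5}$ and $5.5\times10^{-5}$
mol/L), and water and protons excluded from the sum entirely. The sum runs
over *species occurrences*: a compound present in two compartments of one
reaction contributes one term per species. Compounds are matched by base
identifier (`h`, `h2o`, `h2`, `o2` by default), not by formula — model
identifiers are the only reliable key. Energies are carried in kcal/mol by
default; the unit is a configuration field propagated to every output,
since different energy tables come in different units. Transport-energy
contributions (membrane potential, proton gradient) are accepted as an
optional additive per-reaction `offset` column of the input table; the
package does not model them.

## Flux distribution

Fluxes come from flux balance analysis: maximize the biomass objective
subject to $S v = 0$ and bounds. The LP is solved by the package's own
two-phase bounded-variable primal simplex with Bland's smallest-index
anti-cycling rule — deterministic by construction, with the solver identity
recorded in the result metadata. The steady-state residual
$\lVert S v\rVert_\infty$ is checked against a $10^{-9}$ feasibility
tolerance after every solve.

FBA optima are almost always degenerate: the optimal *value* is unique,
the optimal *vector* is not, and every downstream weight depends on the
whole vector. The package therefore offers a parsimonious secondary step
(`pfba = TRUE`): among the optima, return the vector minimizing total flux
$\sum_i |v_i|$. The acceptance workflow uses this representative; exact
per-reaction flux identity with any other solver's output is explicitly
not promised, only the optimal objective and aggregate energy sums.

## Weights and the free-energy balance

The weight of reaction $i$ is its free-energy dissipation rate
$$w_i = \Delta G^{m}_i \; v_i \qquad
  [\text{kcal gDW}^{-1}\text{h}^{-1}],$$
the energy change per mole times the moles converted per unit time. Fluxes
(and weights) below $10^{-9}$ in magnitude snap to exactly zero before any
binning: LP solvers emit $O(10^{-12})$ noise that would otherwise empty the
dominant zero-weight class of the histogram. Histogram bins are built from
interior edges that must bracket zero; the convention is half-open
$[lo, hi)$ bins on the negative side, an exact-zero bin, and $(lo, hi]$
bins on the positive side, so every weight lands in exactly one bin. The
published tables force an exact-zero class but do not state edge openness;
this convention is the package's choice and is documented here rather than
guessed elsewhere.

The network export is the standard bipartite species–reaction graph
(species nodes typed `metabolite`, reaction nodes typed `reaction` carrying
$w$; edge direction follows coefficient sign). A reaction-adjacency
projection (reactions sharing a metabolite, edge weight the mean of the two
$w$) is available behind a flag.

At nonequilibrium steady state the free energy dissipated inside the system
balances the input from the environment. With $R_{met}$ the internal
(reconstructed) reactions and $R_{ex}$ the exchange reactions:
$$G_{sys} = \sum_{i \in R_{met}} \Delta G^m_i v_i, \qquad
  G_{env} = \sum_{j \in R_{ex}} \Delta G^m_j v_j, \qquad
  G_{phy} = -(G_{env} + G_{sys}).$$
The biomass pseudo-reaction belongs to neither sum. $G_{phy}$ is an
*estimate by difference*, never an independently computed quantity. The
energy of an exchange reaction $A \leftrightarrow \varnothing$ is computed
from its own stoichiometry ($-s_A \Delta G_f(A)$, millimolar-adjusted) —
the source model does not define it otherwise, and the convention is
recorded in the output metadata. Fractions are reported as signed shares
$-G_{sys}/G_{env}$ and $-G_{phy}/G_{env}$ (in percent): these sum to 100%
identically by the three-term identity, and coincide with the magnitude
ratios $|G_{sys}|/|G_{env}|$, $|G_{phy}|/|G_{env}|$ whenever both
dissipation terms oppose the input's sign, which is the physically expected
regime.

## What the synthetic generator emulates

Every module is exercisable without external files through
`generateSyntheticModel()`. The default study conditions, fixed once:

| parameter | default | why |
|---|---|---|
| compounds | 30 | smallest size at which the masked system is comfortably overdetermined |
| compartments | 2 (+ extracellular) | exercises shared formation energies across compartments |
| random internal reactions | 60 | ~2 constraints per compound on average |
| exchange reactions | 6 | one open uptake + secretions, minimal-media-like |
| masked compounds | 20% | same order as the published unknown share (16%) |
| masked reaction energies | 25% of unknown-touching rows | mirrors the published 81/(81+244) split |
| coefficients | $\{-2,-1,1,2\}$ | small integers mirror real models, keep hand-checks feasible |
| participants per reaction | mean 4 | typical reaction arity |
| noise | 0 (sd in kcal/mol when set) | noise-free recovery is the primary check |

Formation energies are uniform on $[-200, 50]$ kcal/mol; reaction energies
follow from the stoichiometry. Random reactions are *mass-balanced*
(reactant and product coefficient sums equal, unit compound masses), so no
reaction loop can create matter and the planted
uptake→transport→chain→biomass path (uptake bound 10) pins the FBA optimum
at exactly 10. Gaussian noise, when enabled, is applied to the released
energies of the *constraint rows* only — reactions fully covered by known
formation energies stay self-consistent, exactly as group-contribution
reaction energies derived from the same formation table are. Noise draws
are taken from the RNG stream unconditionally and scaled, so two
generations at one seed differing only in `noise_sd` share their noise
pattern and recovery error scales exactly linearly.

What the generator does **not** emulate: real pathway structure, realistic
flux magnitudes, correlated group-contribution errors, thermodynamically
consistent reaction directions, or transport energetics. Passing tests
demonstrate the algebra and the solvers, not biological fidelity on real
reconstructions.

```{r example}
gen <- generateSyntheticModel(syntheticSpec(seed = 1))
res <- completeEnergies(gen$model, gen$masked)
res$inference
res$report
flux <- solveFBA(fluxProblem(gen$model), pfba = TRUE)
flux
bal <- energyBalance(res$tables, flux, gen$model)
bal
```

## Degenerate inputs and edge behaviour

* No unknown compounds: the transfer matrix has zero columns and inference
  is a warning-carrying no-op; completion is idempotent.
* Unknowns with no constraint row: an error naming the unconstrained
  compounds (an underdetermined system is not silently "solved").
* Constant weight or flux vectors: the weight–flux Pearson correlation is
  flagged undefined instead of erroring.
* Zero flux everywhere: all balance terms are exactly zero and the
  fractions are undefined (`NA`).
* Species identifiers that match neither the bracket (`atp[c]`) nor the
  SBML (`M_atp_c`) dialect map to themselves in lenient mode and error in
  strict mode.

## Problem sizes used in the checks

The shipped tests and the acceptance workflow run on the default synthetic
conditions above (76 reactions, ~40 species) and on hand-sized toys whose
optima and adjustments are verified against enumeration and closed forms; a
full genome-scale run (1668 species, 2382 reactions) uses the same code
paths through sparse algebra and completes in minutes, but requires the
published model file, which cannot be redistributed here.

## Known limitations

* The transmembrane electrochemical/proton-gradient contribution to
  transport reaction energies is input (`offset`), not modelled.
* No propagation of group-contribution standard errors into the inferred
  energies; the consistency report and the weakly-determined flags are the
  only uncertainty signals.
* FBA alternate optima mean per-reaction fluxes (hence individual weights)
  are representative, not unique; aggregate sums are the robust outputs.
* No pH/ionic-strength transforms beyond the concentration adjustment, and
  no thermodynamic constraints inside the LP.
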