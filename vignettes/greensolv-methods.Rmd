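---
title: "Models and methods behind greensolv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind greensolv}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(greensolv)
library(dplyr)
```

`greensolv` implements a screening protocol for finding solvents that are
simultaneously effective (high predicted solubility of a target solid) and
environmentally benign (low composite impact index), plus the follow-up
analysis of water–organic binary mixtures. This vignette explains the
models, the parameter choices that were genuinely open, and what the
package's validation does and does not demonstrate.

## Solid–liquid equilibrium model

A crystalline solute dissolved to saturation satisfies

$$\ln\!\left(\gamma^{sat} x^{sat}\right)
  = -\frac{\max\!\left(0,\ \Delta_{fus}G\right)}{RT},$$

where $x^{sat}$ is the saturation mole fraction, $\gamma^{sat}$ the
solute's activity coefficient at that composition, and $\Delta_{fus}G$ the
partial molar Gibbs energy of fusion. We adopt the standard simplification
that the heat-capacity change on melting is negligible, so

$$\Delta_{fus}G(T) = \Delta_{fus}H \left(1 - T/T_m\right),$$

requiring only the melting temperature $T_m$ (K) and enthalpy of fusion
$\Delta_{fus}H$ (kJ/mol) per solute. The clamp at zero encodes that above
$T_m$ the pure solute is already liquid: the right-hand side becomes
$\ln 1 = 0$ and the ideal-solution solution is complete miscibility.
With $\gamma = 1$ the closed form $x^{id} = \exp(-\Delta_{fus}G/RT)$
follows; `ideal_solubility()` exposes it and the solver must reproduce it
exactly under the ideal model (a cross-module oracle in the test suite).

**Units.** One unit system internally: kelvin, kJ/mol, and
$R = 8.31446\ \mathrm{J\,mol^{-1}K^{-1}}$. Conversions (notably
kcal/mol $\to$ kJ/mol, factor exactly 4.184) happen only at catalog
boundaries with an explicit unit tag, never by inference.

**A note on the bundled fusion constants.** The literature source for the
three bundled amides prints their fusion enthalpies with a kcal/mol tag,
but the magnitudes (20.9, 28.4, 20.4) are the values the thermochemical
compilations report in kJ/mol, and only the kJ/mol reading produces
sensible ideal solubilities (benzamide: 0.115 rather than $4\times
10^{-10}$). The bundled records therefore declare kJ/mol; the unit tag
remains mandatory and explicit everywhere so the literal reading is one
argument away.

## Activity-coefficient models

The solver needs only a map from composition to $\ln\gamma$ of the solute,
with the pure-liquid reference state ($\ln\gamma_i \to 0$ as
$x_i \to 1$). First-principles continuum-solvation engines (COSMO-RS and
kin) fit this contract but their parameterizations are commercial and not
reproducible here; the package deliberately specifies the *contract* and
ships three transparent engines:

* **ideal** — $\ln\gamma = 0$; the reference limit.
* **Margules (two-suffix / regular solution)** — binary
  $\ln\gamma_1 = A x_2^2$; multicomponent form derived from
  $G^E/RT = \sum_{j<k} A_{jk} x_j x_k$, i.e.
  $\ln\gamma_i = \sum_j A_{ij}x_j - G^E/RT$, which reduces to the binary
  closed form and satisfies Gibbs–Duhem by construction. A single
  symmetric parameter per pair makes it the natural vehicle for
  constructed test systems (a negative solute–solvent $A$ means
  favourable interactions, hence above-ideal solubility).
* **NRTL** — the standard multicomponent expression over user-supplied
  $\tau$ and $\alpha$ tables. Temperature dependence is *not* built in
  ($\tau = a + b/T$ forms vary by source); callers supply $\tau(T)$
  tables, avoiding invented parameter physics.

Both nonideal engines are property-tested: Gibbs–Duhem
($\sum_i x_i\, d\ln\gamma_i/dx_1 \approx 0$ by central differences,
tolerance $10^{-6}$), the pure-component limit, permutation symmetry, and
the binary NRTL infinite-dilution identity
$\ln\gamma_1^\infty = \tau_{21} + \tau_{12} e^{-\alpha\tau_{12}}$.

## The fixed-point solver

The saturation condition is solved by damped fixed-point iteration in
$\ln x$:

$$\ln x^{(k+1)} = (1-d)\,\ln x^{(k)} +
  d\left[\ln a^{sat} - \ln\gamma\!\left(x^{(k)}\right)\right],
  \qquad a^{sat} = e^{-\max(0,\Delta_{fus}G)/RT}.$$

Numerical choices, each made once:

* **Initialisation** at the ideal solubility: in the $\gamma\approx 1$
  regime the start *is* the fixed point and the solver converges in one
  step.
* **Damping** $d = 0.5$ by default. The undamped map has local
  contraction factor $|2Ax(1-x)|$ for a binary Margules system, which
  exceeds 1 for strongly favourable interactions; halving the step
  restores convergence there while results for convergent cases are
  independent of $d$ (tested over $d \in \{0.25, 0.5, 1\}$).
* **Stopping** at $|\Delta\ln x| < 10^{-10}$ (relative change in $x$),
  500 iterations maximum; non-convergence is reported in the result
  (`converged = FALSE`), never thrown, so batch screens don't die on one
  pathological solvent.
* **Miscibility cutoff** at $x = 0.9999$: an iterate reaching the
  pure-liquid limit is declared miscible and reported as $x_{sat} = 1$
  with a flag. Continuum-solvation packages report this situation as
  "infinite solubility"; the exact internal criterion they use is
  undocumented, so the cutoff is this package's declared substitute. The
  flag maps to $+\infty$ on the $\log_{10}$ scale so such solvents sort
  first in rankings.
* **Composition bookkeeping**: mixed solvents are specified on a
  solute-free basis ($x_2^*$, the organic fraction of the water–organic
  pair) and renormalised against the current solute fraction each
  iteration, matching the composition convention of shake-flask work in
  binary solvents.

The solver is validated against an independent interval-bisection oracle
on $\gamma(x)\,x = a$ over 50 seeded random Margules and NRTL binaries
(agreement to $|\Delta x| < 10^{-8}$), plus the exact ideal closed form.

## Environmental index

Each solvent carries eight nonnegative impact scores — human toxicity by
ingestion (HTPIng) and inhalation (HTPInh), terrestrial (TTP) and aquatic
(ATP) toxicity, global warming (GWP), ozone depletion (ODP), photochemical
oxidation (PCOP) and acid rain (AR) — on the scale printed by the EPA's
PARIS III solvent-substitution tool. The composite EI is their plain sum;
this aggregation is validated by reproducing the printed composites of the
bundled solvents from their printed components (DMF 2.16, 4FM 0.51, DMSO
without PCOP 0.26, each within ±0.01). Published tables display HTPIng
×10 and ATP ×10⁵; the catalog reader de-scales such columns at load when
the header declares them (`htping_x10`, `atp_x1e5`), and the writer can
re-scale for display parity. Impact weighting beyond what is folded into
the printed scores is *not* reapplied — only the printed scale is
recoverable.

The **PCOP-excluded variant** exists because smog-formation potential is
arguably irrelevant for low-volatility solvents handled in closed
equipment; DMSO is the canonical case (PCOP dominates its EI: 11.4 of
11.7).

**Aqueous mixtures** combine composites by mass fraction:
$w = x M_{org} / (x M_{org} + (1-x) M_{water})$ and
$EI_{mix} = w\,EI_{neat} + (1-w)\,EI_{water}$ with $EI_{water} = 0.02$.
The source tables never state the combination rule; mass-fraction
weighting is the unique simple rule consistent with all twelve published
mixture rows (worst absolute deviation ≈ 0.03, attributable to 2-decimal
rounding), whereas mole-fraction weighting misses the low-fraction DMSO
row by over 3 EI units. Mixing operates on composites, not components,
because water's component-level breakdown is not published — inventing
eight unprinted numbers would be worse than the small residuals this
leaves (e.g. neat DMSO component sum 11.66 vs printed composite 11.70).

Rankings sort ascending per variant, with exact ties broken
lexicographically by label and flagged.

```{r}
example_greenness_table() |>
  select(system, ei_default, ei_no_pcop, rank_default, rank_no_pcop) |>
  head(8)
```

## Screening cascade

`screen_catalog()` applies, in order: commercial availability; a *strict*
EI ceiling (default `ei_max = 2`, so EI = 2 exactly is excluded);
predicted solubility in every survivor with a per-solvent activity model.
Candidates are flagged when their predicted $\log_{10} x_{sat}$ strictly
exceeds the reference solvent's (methanol by default). Two choices here
were genuinely open:

* The better-than-reference comparison is made in *computed*
  log-solubility space, not experimental: screening runs before any
  measurement exists, and the reference's value is computed from its own
  catalog record regardless of whether it passes the filters.
* Miscible predictions are kept as a labelled category ranked first
  rather than assigned a numeric value — "infinite solubility" is a
  qualitative statement of very high solubility, not a number.

Solvents lacking EI data are excluded with a warning and counted
separately rather than silently dropped. `shortlist_binary_grids()`
couples each shortlisted solvent's aqueous solubility profile with the
mixture EI at the same composition, giving the solubility-vs-greenness
trade-off table that motivates binary-mixture recommendations.

## Mixture classification

`detect_synergy()` calls a profile synergistic when its maximum lies at an
interior solute-free fraction and exceeds **both** endpoint means by more
than 5% relative. The published record gives only a qualitative
"significant" for the co-solvation effect; 5% is this package's declared
default, exposed as `rel_tol`, and sized to sit well above triplicate
shake-flask noise (cv ≈ 3%) while catching the real effects, which are
tens of percent. `antisolvent_classification()` labels a profile
water-antisolvent when mean solubility never decreases with organic
fraction within a one-sided tolerance of one pooled replicate standard
deviation; anything neither monotone nor synergistic is irregular.

`order_solvent_power()` renders orderings like `DMF > 4FM ~ DMSO`:
consecutive solvents (sorted descending) merge into a `~` group when
their means differ by under 5% relative or their ±1 SD intervals overlap.
This reproduces the observed distinction between solutes whose aprotic
solvents separate cleanly and those with a near-tie, without inventing a
formal significance test the underlying triplicates could not support.

## Synthetic data

The generators exist so every pipeline stage is testable offline, with
known ground truth.

* `generate_solvent_catalog()` emulates a large screening database:
  log-normal EI components (totals spanning well below and far above the
  EI = 2 ceiling, as in real impact databases), uniform molar masses in
  18–200 g/mol, Bernoulli availability (default probability 0.7), and a
  per-solvent binary Margules parameter in $[0.5, 3]$ (unfavourable) for
  decoys. *Planted* passers are constructed to survive every filter:
  forced available, components rescaled to a composite in $[0.1, 1.5]$,
  and $A \in [-3, -1]$ so their predicted solubility strictly beats the
  ideal-behaving methanol reference. Recovery of the planted set is
  therefore exact by construction — the test validates the cascade's
  bookkeeping, not a statistical property.
* `generate_measured_profiles()` emulates triplicate shake-flask assays:
  replicate $k$ is $x_{true} e^{\varepsilon_k}$ with
  $\varepsilon_k \sim N(0, cv^2)$. The noise is multiplicative because
  solubilities span orders of magnitude, must stay positive, and
  spectrophotometric assay error is relative. The default $cv = 0.03$
  with $n = 3$ replicates is a declared emulation of typical shake-flask
  error-bar magnitudes (the source reports SD bars but not their values).
  Temperatures default to the 298.15–313.15 K range and the composition
  grid to $\{0, 0.2, ..., 1.0\}$ in the examples, matching standard
  practice.

Inversion checks close the loop: a Margules $A = 1.5$ is recovered within
5% by grid search from noisy triplicates over four temperatures, and a
ternary construction with an interior activity-coefficient minimum at
$x_2^* = 0.6$ is classified synergistic at the true argmax in ≥95% of 200
seeded repetitions.

**What the synthetic data does not emulate:** real impact-score
correlations between components (they are drawn independently),
solvent-specific temperature dependence of $\gamma$, solvate or polymorph
formation (the experimental systems showed none, and the package assumes
a stable solid phase), and assay-specific systematics (calibration drift,
filtration losses). Passing the recovery tests therefore demonstrates
internal consistency of solver + generator + classifier, not predictive
accuracy for laboratory data.

## Problem sizes and determinism

The validation suite runs on deliberately small problems: catalogs of
~200 solvents, 50-case solver/oracle sweeps, 200-repetition synergy
recoveries, and 1000-point noise calibrations — sizes chosen so the full
suite completes in well under a minute while leaving the statistical
checks comfortably powered. All stochastic tests fix their seeds; the
generators take one integer seed per call and are bit-reproducible given
it.

## Known limitations

* The activity models shipped are stand-ins with transparent physics; no
  first-principles parameterization is included, so absolute predicted
  solubilities for real solvent chemistries are only as good as the
  parameters supplied.
* EI mixing on composites cannot resolve component-level mixture
  reporting; residuals of order 0.03 against 2-decimal published tables
  are expected and accepted.
* The synergy classifier works on grid means; it locates the best *grid
  point*, not a continuous optimum between points.
* No solid-phase transformations: solutes with solvate-forming or
  polymorphic tendencies violate the model's assumptions.
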