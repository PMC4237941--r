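---
title: "The couplet-cell simulator: model, calibration and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The couplet-cell simulator: model, calibration and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctcsim)
```

## The model

`ctcsim` simulates a pair of cell populations — *couplet cells* — that arise
from one asymmetric division of a progenitor and thereafter regulate each
other through a pair of secreted signalling molecules ("Trefones").  The
`A` family secretes the `a` Trefone and carries the receptor for the `i`
Trefone; the `I` family is the converse; neither family carries the receptor
for its own product.  The two Trefones associate reversibly into a binary
complex (the canonical example is a growth factor and its soluble binding
protein, e.g. IGF-I and an IGFBP):

$$a + i \rightleftharpoons a{:}i, \qquad
K_a = \frac{[a{:}i]}{[a]_F\,[i]_F} = 10^{10}\ \mathrm{L/mol\ (default)}.$$

Binding is treated as instantaneous relative to one simulation step: only
the association constant is specified by the model, so on/off kinetics are
below its resolution.  Free and bound concentrations follow from totals by
the quadratic mass-action equilibrium (`equilibrate_pair()`), computed in a
cancellation-free form so that very tight binding ($K_a$ up to $10^{16}$)
keeps full precision.  A competitive analog of one Trefone — modelled on
des(1–3)IGF-I, which activates the receptor normally but binds the partner
only weakly — is handled by a one-dimensional bisection on the shared free
species (`equilibrate_with_analog()`).

Each cell reads the world through receptor-mediated uptake: a linear
fractional clearance of the free partner Trefone, plus a much smaller
clearance of the extracellular complex through a scarce complex receptor
(`tccr_count_scale`, default 0.05 — the complex receptor "need only be very
low" because the complex is the most abundant species).  Internalized
material re-equilibrates in a fixed endosomal volume; the resulting
*(free partner, complex)* concentration pair is the cell's readout.  In the
**EC** variant the complex is sampled extracellularly by the complex
receptor; in the **IC** variant no complex receptor exists and the complex
instead forms intracellularly between a hived-off fraction of the cell's own
synthesis and the internalized partner Trefone.

The readout is discretized into Lo/Mid/Hi per channel (half-open bins,
boundary in the upper bin) and drives a total decision table
(`default_table()`):

| partner | complex | immediate | prolonged |
|---|---|---|---|
| Hi | Lo/Mid | boost secretion | symmetric division (SCD) |
| Lo | Lo | quiesce, damp secretion | asymmetric division, escalating |
| any | Hi | quiesce | quiesce (apoptosis at extreme complex + Hi partner) |
| Mid | Mid | quiesce | quiesce, basal AsCD at probability 0.01 |

"Prolonged" means the same readout class has persisted for `dwell_required`
consecutive steps.  Starvation escalates: asymmetric self+partner division at
one dwell, two partner-type cells at `escalation_mult` dwells, and
dedifferentiation to the progenitor (`O`) at `dediff_mult` dwells; a division
trigger and the dedifferentiation threshold landing on the same step resolve
in favour of division (dedifferentiation is the last resort).  `O` cells
carry both receptors weakly (a repo convention — the source model never
specifies progenitor receptors) and recommit by dual lineage commitment as
soon as any Trefone signal is present.  The immune `SINGLET` is a
half-couplet: it secretes an antibody-like Trefone against an exogenous
antigen, divides when antigen is high and the immune-complex readout is not,
and never divides asymmetrically (there is no partner type to produce).

## Units, scales and the default calibration

Concentrations are mol/L throughout; pool state is kept as amounts (mol) in
a well-mixed compartment of volume $10^{-9}$ L.  The source model publishes
no concentrations (its worked concentration table lives in supplementary
material that the main text does not reproduce), so the defaults are chosen
once, as a self-consistent "stated world", and then frozen:

* `secretion_rate` $= 10^{-18}$ mol/step/cell → 1 nM/step in the 1 nL pool.
* `degradation_rate` $= 0.35$/step: a population of $N$ secreting cells
  holds a steady-state total of $\approx 2.9\,N$ nM.
* `uptake_rate` $= 0.005$/step/cell.  Uptake must be *perturbative*: with
  aggressive uptake the populations themselves clamp the free levels and the
  imbalance signal (free partner ∝ production surplus) is destroyed.
* `store_decay_rate` $= 0.5$/step: internalized signal is consumed quickly,
  so the readout tracks the pool with a ~2-step lag.
* endosome volume $10^{-13}$ L.  At the uptake/turnover steady state a pool
  concentration $c$ maps to a partner readout of
  $c \cdot u V / (\lambda_s V_e) = 100\,c$ and a complex readout of
  $5\,c$ (the extra 0.05 is the complex-receptor scarcity).
  `pool_thresholds()` exposes this pullback; every scenario assertion about
  the extracellular state uses it rather than ad hoc constants.

The decision thresholds are set on the readout scale from three
requirements: (i) the balanced steady state of ~20+20 cells must read
(Lo partner, Mid complex) → quiescence; (ii) a production surplus of a few
cells' worth must push the partner channel to Hi; (iii) the complex channel
must reach Hi at roughly twice the default population (the carrying brake),
and fall to Lo when the smaller family's total collapses.  With the mappings
above this gives `theta_lo/hi_partner` $= 4\times10^{-7}/10^{-6}$ and
`theta_lo/hi_complex` $= 1.8\times10^{-7}/4.5\times10^{-7}$ mol/L.  Free
levels near $1/K_a = 10^{-10}$ M pool-side are deep in the Lo bin, as
intended.

**Dwell.** `dwell_required` defaults to 8 steps.  An earlier draft used 5,
but divisions are population doublings and the pool (τ ≈ 3 steps) and store
(τ ≈ 2 steps) lags mean a stimulus outlives its cause by ~5 steps; with a
5-step dwell the responding family reliably overshot by one doubling and the
couplet oscillated.  A dwell comfortably longer than the total lag lets the
readout catch up between doublings, and the homeostat then converges without
overshoot.  The secretion boost (`boost_factor` = 0.2) is kept mild for the
same reason: the boosted and quiescent production levels must map to the
same side of the complex thresholds, or the carrying brake engages during
growth at a different population than it releases at rest.

**The fixed point and its spike response.** At rest the couplet sits at
(Lo partner, Mid-to-Hi complex) and only quiesces.  A spike of one Trefone
drives the opposite family's partner channel Hi while the complex — bounded
by the *smaller* family's total — stays Mid, so symmetric divisions fire
until either the surplus is consumed or the complex brake engages.  Because
the complex tracks the limiting family, the brake engages precisely as the
deficient family catches up: the terminal state has a high complex and low,
near-equal free Trefones.  A fully saturated Hi-complex state is
deliberately unresponsive ("high complex inhibits growth"); scenarios perturb
from the operating band.

## What the scenarios establish — and what they do not

Seven frozen configuration+seed fixtures reproduce the model's narrated
thought experiments: spike recovery (`scenario_balanced_perturbation`),
monoculture conversion, low-affinity analog potency, an acute Trefone sink,
the deterministic embryonic lineage (50% receptor-positive blastomeres at
the 2-, 4- and 8-cell stages), persister kill-and-regrowth, and the singlet
immune cell.  Every asymmetric scenario also runs with the couplet roles
swapped (`mirror = TRUE`); the implementation is symmetric in the two
species, including the analog orientation, so the mirrored assertions must
pass identically.

The generator emulates a well-mixed, spatially unstructured world with
deterministic synchronous updates, a single RNG stream consumed in cell-id
order, and equal partitioning of internal stores at division.  It does not
emulate: spatial gradients or juxtacrine contact, receptor synthesis and
recycling dynamics, saturating (Michaelis-type) uptake, cell-cycle phase
structure, asymmetric cytoplasmic partitioning, or any quantitative fit to a
real IGF/insulin dataset.  A green scenario therefore establishes that the
qualitative feedback architecture produces the narrated behaviour under the
stated world — not that the rate constants are biologically measured.

Scenario-specific departures from the default world are part of the stated
fixtures: the persister flask clears its medium at 0.1/step instead of 0.35
(a culture flask is not a tissue interstitium, and the scenario's premise is
that the medium Trefone outlasts the growth phase), and the analog scenario
doses continuously for 30 steps so that the equilibrium contrast — genuine
Trefone sequestered, analog free — persists across a dwell window.

## Numerical choices

* Quadratic root: the smaller root is physical; computed as
  $2q/(b + \sqrt{b^2 - 4 k_a q})$ to avoid catastrophic cancellation.
* Analog equilibrium: bisection on free `i` to a relative bracket of
  $10^{-13}$; the residual is strictly increasing so the root is unique; a
  200-iteration cap raises an error reporting the residual.  Tests verify it
  against an independent `polyroot` solution of the equivalent cubic.
* Mass ledger: for each species, cumulative (initial + added + secreted) =
  pool total + Σ cell stores + cumulative degraded, checked to $10^{-9}$
  relative after *every* step; violation is a hard error, not a warning.
  Apoptosis and kill events destroy internal stores into the degradation
  ledger rather than returning them to the pool.
* Discretization boundaries go to the upper bin; dwell counters increment on
  the step being classified, so a threshold-equal readout is reproducible.
* Event ordering within a step is fixed: secrete → degrade (pool, then
  internal turnover) → equilibrate → uptake (id order, clipped against the
  remaining pool) → readouts → decisions on the same snapshot → divisions →
  due events → ledger check → record.

## Open design points resolved here

* **"TD/SCD"** is implemented as one division yielding two partner-type
  cells (`TD_SCD`), the same outcome as the starved escalation
  `ASCD_PARTNER_PARTNER` but available as an explicit action.
* **Dormancy**: dormant cells neither secrete nor act, but their receptors
  keep working — a dormant persister must be able to *sense* the fresh
  medium that reawakens it (Hi partner readout).  Kill events
  (`KILL_CYCLING`) remove every non-dormant live cell, quiescent ones
  included: quiescent cells are metabolically active and antibiotic
  treatment in the persistence story spares only the growth-arrested state.
* **Blastomere marker**: "receptor-positive" counts the committed profile
  (`aR+ iR-`); the progenitor carries both receptors, so the
  symmetric-first-cleavage ablation control yields zero positive cells at
  every stage, as it must.
* **IC complex sequestration**: IC-variant cells internalize no complex
  (no receptor for it), but the extracellular complex still sequesters free
  Trefone in the pool equilibrium.
* **The analog's receptor**: the analog is taken up by the receptor for the
  species it imitates, and the scarce complex receptor internalizes the
  analog complex at the same scale — this makes an analog with
  $k_{a,\mathrm{analog}} = K_a$ exactly indistinguishable from the genuine
  Trefone, which the degenerate-equality test asserts.

## Known limitations

Population changes are cohort doublings, so sub-10% balance claims need the
basal asymmetric-division trickle to break ties; very small populations
(< ~10 per family) can self-starve into the asymmetric-division regime
before settling (the model's own account of regeneration, but worth knowing
when designing configurations).  Runtime is interpreted R: ~1 ms per
cell-step; desk-scale worlds (≤ a few hundred cells, ≤ a few hundred steps)
run in seconds.

```{r example}
report <- scenario_blastomere_lineage()
report$observables$percent_positive
```
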