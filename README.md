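# ctcsim

An agent-based simulator of **couplet cells**: two cell populations, born
from one asymmetric division of a progenitor, that regulate each other's
metabolism, proliferation and fate through a pair of secreted signalling
molecules ("Trefones") that bind each other into a reversible binary
complex.  The canonical instance is a growth factor and its soluble binding
protein (IGF-I and an IGFBP): the `A` family secretes the `a` Trefone and
carries the receptor for the `i` Trefone, the `I` family the converse, and
each cell decides its fate from an internalized readout of **free partner
Trefone** and **complex**.

The package is aimed at systems-biology readers who want the couplet
feedback architecture as a runnable, testable object: what follows from
"each cell counts its partner family by measuring one Trefone *and* the
complex", under explicit mass-action chemistry and an explicit, overridable
decision table?

## The model in brief

Extracellular binding follows mass action at association constant
*K*ₐ (default 10¹⁰ L/mol):

    a + i ⇌ a:i,   Ka = [a:i] / ([a]F [i]F)

Per step, each live cell secretes its Trefone, the pool degrades
first-order, the pool re-equilibrates, cells internalize a small fraction of
their free partner Trefone (plus a much smaller fraction of the complex,
through a scarce complex receptor), and the internalized material
re-equilibrates in an endosomal volume.  The resulting
(partner, complex) concentration pair, discretized Lo/Mid/Hi, drives a
decision table:

* **Hi partner, complex not Hi** — partner family in excess: boost
  secretion; if sustained, divide symmetrically.
* **Lo partner, Lo complex** — partner family deficient: quiesce with damped
  secretion; if sustained, divide asymmetrically to regenerate the partner
  family, escalating eventually to dedifferentiation.
* **Hi complex** — both families abundant: quiesce (growth inhibition);
  apoptosis at extreme complex.

Two variants are implemented: **EC** (extracellular complex sensed by a
scarce membrane receptor) and **IC** (complex formed intracellularly from a
hived-off fraction of the cell's own synthesis).  A competitive low-affinity
analog (des(1–3)IGF-I-style) and a `SINGLET` immune half-couplet
(antibody vs. exogenous antigen) are first-class citizens.

Every run keeps a per-species **mass ledger** (secreted + added = pool +
cell stores + degraded, to 10⁻⁹ relative) that is verified after every step.

## Worked example

```r
library(ctcsim)

# tight binding leaves ~90% of equal totals in the complex
equilibrate_pair(1e-8, 1e-8, ka = 1e10)
#> Trefone couplet equilibrium (mol/L)
#>   free a      : 9.51249e-10
#>   free i      : 9.51249e-10
#>   complex a:i : 9.04875e-09

# homeostasis: spike one Trefone into a balanced couplet world
report <- scenario_balanced_perturbation(seed = 1)
report
#> Scenario 'balanced_perturbation' (seed 1, config 32a83970): PASS
#>   [ok] focal family rises within the dwell window — I: 40 -> 80 (steps 20..44)
#>   [ok] population ratio rebalances below 0.1 — final |N_A - N_I|/(N_A + N_I) = 0.000
#>   [ok] terminal Hi complex with low, near-equal free Trefones — complex 1.26e-07
#>        (Hi >= 9e-08), free a 3.55e-09 / i 3.55e-09 (low < 1e-08), gap 0.00
```

The spiked `a` Trefone makes the `I` family read "partner excess" and double
twice (40 → 80); as the spike decays the `A` family sees the surplus `i`
Trefone and catches up (40 → 80); the run ends with equal populations, a
high complex and low, equal free Trefones — the couplet fixed point.

Other canned scenarios: `scenario_monoculture_conversion()` (one family +
its own Trefone regenerates the other), `scenario_analog_potency()` (the
weakly-bound analog out-stimulates the genuine Trefone because it escapes
sequestration), `scenario_trefone_sink()` (acute destruction of one
Trefone), `scenario_blastomere_lineage()` (deterministic embryonic lineage:
exactly half the blastomeres carry the partner-Trefone receptor at the 2-,
4- and 8-cell stages), `scenario_persisters()` (dormant cells survive a kill
event and regrow both families), `scenario_singlet_immune()` (antibody
production plateaus when the immune-complex readout goes Hi).  All accept
`mirror = TRUE` to swap the couplet roles.

Custom worlds are JSON documents (see `inst/extdata/example_couplet.json`)
loaded with `load_config()`; `ctc_run()` returns the full trajectory as a
data frame plus cumulative action tallies and the ledger.  A command-line
front end ships in `inst/cli/ctc-sim`:

```sh
inst/cli/ctc-sim run inst/extdata/example_couplet.json --out outdir
inst/cli/ctc-sim scenario balanced_perturbation --seed 1 --mirror
inst/cli/ctc-sim equilibrate --ka 1e10 --total-a 1e-8 --total-i 1e-8
inst/cli/ctc-sim validate my_config.json
```

Exit codes: 0 success, 1 scenario assertion failure, 2 validation error.

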