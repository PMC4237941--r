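Package: ctcsim
Title: Simulation of Couplet-Cell Populations Coupled by Trefone Binding Pairs
Version: 0.1.0
Authors@R:
    person("CTC", "Maintainers", email = "ctcsim@example.org", role = c("aut", "cre"))
Description: A time-stepped, agent-based simulator of two cell populations
    produced by asymmetric cell division that communicate through a pair of
    secreted signalling molecules ("Trefones", e.g. a growth factor and its
    soluble binding protein) forming a reversible binary complex.  Provides
    closed-form and iterative mass-action equilibrium solvers (including a
    competitive low-affinity analog), receptor-profile cell typing, a
    configurable rule table mapping each cell's internalized readout of free
    partner Trefone and complex to fate decisions (secretion boost, symmetric
    or asymmetric division, transdifferentiation, dedifferentiation,
    quiescence, apoptosis), a deterministic world loop with a per-species mass
    ledger, and canned scenarios exercising homeostasis, monoculture
    conversion, low-affinity analog potency, acute ligand sinks, embryonic
    lineage marker fractions, persister regrowth and a singlet immune cell.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
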