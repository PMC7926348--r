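Package: porelattice
Title: Statistical and Linear-Response Modelling of Multi-Ion Conduction
    in Narrow Channel Pores
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Equilibrium and linear-response theory for ion permeation
    through a selectivity filter modelled as a short one-dimensional
    lattice of binding sites exchanging ions with bulk reservoirs.
    Provides exact grand-canonical enumeration of pore configurations,
    free energies with an electrostatic self-energy (ionic Coulomb
    blockade), site occupancies and fluctuations, susceptibilities to
    electrical and chemical gradients, per-site conductivities and the
    series current, entry barriers and resonant-charge analysis, least
    squares estimation of site excess chemical potentials from occupancy
    and current data, a whole-cell normalized IV pipeline with effective
    open-probability estimation, and generators for synthetic occupancy,
    single-channel IV and whole-cell datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
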