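Package: resistevol
Title: Evolution of Insecticide Resistance in Malaria Mosquitoes under
    Bed Nets and Larvicides
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Deterministic two-sex population-genetic model of the
    evolution of insecticide resistance in malaria vectors. Genotype
    fitnesses are derived from a mechanistic model of the mosquito
    feeding cycle (bed-net coverage, repellency, animal feeding,
    insecticide survival, gonotrophic-cycle mortality) together with
    larvicide exposure of the aquatic stages. The package iterates the
    selection recursion over discrete non-overlapping generations,
    classifies fixation or elimination of the resistance allele,
    computes invasion growth factors and coverage thresholds by
    bisection, compares the selection pressure of larvicides and
    insecticide-treated nets, and provides a finite-population
    Wright-Fisher sampling counterpart for verification and drift
    exploration. A command-line interface exposes trajectory
    simulation, threshold finding and the parameter-sweep experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
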