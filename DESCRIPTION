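Package: hennig
Title: Hennigian Argumentation and Parsimony for Polarity-Coded Morphological Characters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for morphological cladistics on binary, polarity-coded
    character matrices of the kind used in Hennigian argumentation studies of
    harpacticoid copepods. Provides a character-matrix data model with
    uncertainty and intraspecific-variability codes, CSV/TSV/NEXUS input and
    output, root-constrained Fitch/Hartigan parsimony on rooted trees with
    polytomies, exact branch-and-bound tree search, homoplasy indices,
    synapomorphy grouping with parsimony-based convergence arbitration,
    construction and validation of dichotomous identification keys, and a
    seeded simulator of binary character evolution with controlled convergence.
    Ships a worked analysis of the benthic copepod genus Laophontodes
    (12 species, 39 characters) including its published character matrix,
    cladogram, and diagnostic key as packaged fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
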