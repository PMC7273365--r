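Package: sitecliffs
Title: Detection of Dual-Site, Isomer and Privileged-Substructure Activity Cliffs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A unified search strategy for three categories of activity
    cliffs in compound-activity data: dual-site cliffs (different
    substituents at different core positions), isomer cliffs (the same
    substituent at two different core positions) and cliffs containing a
    privileged substructure. Compounds are decomposed by systematic
    single cuts of exocyclic single bonds into a hydrogen-capped core and
    a substituent, organized into analog series per target by shared
    core, and screened pairwise for at-least-100-fold potency
    differences. Dual-site cliffs can be extended with repositioned
    structural isomers into a four-compound data structure that exposes
    position-specific contributions to cliff formation. Includes a
    synthetic analog-series generator with combinatorial ground truth for
    end-to-end validation, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    ChemmineOB,
    igraph,
    dplyr,
    rlang,
    tibble,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
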