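Package: myelomaABM
Title: Multi-Scale Agent-Based Simulation of Multiple Myeloma and the
    Osteoblast-Osteoclast Balance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A three-dimensional lattice agent-based model of multiple
    myeloma (MM) cells, osteoblasts (OB) and osteoclasts (OC) coupled
    through the DKK1-Wnt-OPG/RANKL-TNFa signaling axis.  Cells switch
    phenotype (apoptosis, proliferation, migration, quiescence) via
    Hill-function responses to local cytokine and drug fields; cytokines
    and three drugs (the anti-DKK1 antibody BHQ880, glucocorticoids and
    Lidamycin) spread on the lattice by an explicit finite-difference
    diffusion scheme.  The package scores treatment regimens with the
    composite R_drug endpoint, quantifies drug-combination synergy with
    the Loewe combination index, and screens parameter influence with a
    one-at-a-time Spearman sensitivity sweep.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    yaml,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
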