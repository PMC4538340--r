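Package: dra
Title: Docking-Based Rank Aggregation for Virtual Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fuses ranked compound lists produced by multiple docking scoring
    functions into a consensus ranking by cross-entropy minimisation of the
    (weighted) Spearman footrule distance. Rankings are evaluated against a
    reference activity ordering with normalised discounted cumulative gain
    (nDCG) and validated by the detection rate of known positives in the top
    slice of a list. A generic ligand-based 3D pharmacophore engine (typed
    feature detection, assignment matching with tolerance spheres, excluded
    volumes) pre-filters compound libraries before docking. Includes seeded
    generators for correlated noisy scorer ensembles and pharmacophore fixture
    libraries, and a replication harness for published benchmark tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    ChemmineR,
    bio3d,
    optparse,
    yaml,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
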