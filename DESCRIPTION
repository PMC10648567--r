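Package: targan
Title: Ligand-Based Target Fishing and Scaffold-Constrained Analog Optimization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A two-stage in-silico discovery workflow for a query ligand such
    as cannabidiol. Stage one identifies disease-associated protein targets by
    fingerprint-similarity screening of an annotated drug library followed by
    binding-affinity filtering and disease-phenotype intersection. Stage two
    evolves analogs of the query with a scaffold-constrained genetic algorithm
    that minimizes a docking score while enforcing drug-likeness constraints
    (QED, synthetic accessibility, logP, penalized logP) and structural-alert
    filters. Deterministic surrogate oracles and a synthetic-data generator
    with planted ground truth make every stage testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    ChemmineOB,
    Biostrings,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: Cheminformatics, Software
Collate:
    'graph-internals.R'
    'openbabel.R'
    'Molecule.R'
    'fingerprints.R'
    'qed-constants.R'
    'filters.R'
    'properties.R'
    'oracles.R'
    'targetid.R'
    'io.R'
    'ga.R'
    'synthetic.R'
    'report.R'
    'targan-package.R'
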