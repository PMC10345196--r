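Package: funsites
Title: Discovering Functional Sites in Proteins from Stability and
    Conservation Signatures of Variant Effects
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Author: Package Author [aut, cre]
Maintainer: Package Author <author@example.org>
Description: Identifies functionally important residues in proteins by
    classifying amino-acid substitutions into four phenotypic classes
    (wild-type-like, total-loss, stable-but-inactive, low-abundance/
    high-activity) with a gradient-boosting model trained on paired
    abundance/activity deep mutational scanning data. Per-variant
    features combine predicted stability changes, evolutionary
    conservation scores, target-residue hydrophobicity and the weighted
    contact number computed from protein structure. Variant-level
    predictions are aggregated into residue-level functional-site calls,
    including monomer-versus-oligomer comparisons that expose
    protein-protein interface residues. Includes synthetic-data
    generators so the full pipeline can be exercised without external
    predictors.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    xgboost,
    ranger,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse,
    withr
Config/testthat/edition: 3
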