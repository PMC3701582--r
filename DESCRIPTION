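Package: targetfishR
Title: Ligand-Based Protein Target Prediction with Parzen-Rosenblatt Scoring
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Curates heterogeneous bioactivity records into activity-filtered
    compound families, splits them into scaffold-coherent refined families by
    parameter-free clustering of circular-fingerprint Tanimoto similarities,
    and scores query molecules against families with a Parzen-Rosenblatt
    mean-p-value built on a Gaussian transform of Tanimoto similarity.
    Includes Monte Carlo cross-validation with top-k retrieval and Matthews
    correlation statistics, structure- and activity-profile clustering of
    compound panels, and a self-contained synthetic library generator for
    end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    ChemmineOB,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    cluster,
    mclust,
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
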