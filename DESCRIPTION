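Package: ConsensusDiversity
Title: Consensus Diversity Plots for Chemical Library Comparison
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantifies the structural diversity of compound libraries under
    three independent molecular representations - chemotypes (cyclic-system
    scaffolds), structural fingerprints, and physicochemical properties - and
    combines the per-library metrics into a single low-dimensional Consensus
    Diversity Plot with four-quadrant high/low diversity classification.
    Implements cyclic system recovery (CSR) curves with AUC and F50, scaled
    Shannon entropy over the most populated chemotypes, intra-library
    MACCS/ECFP4 Tanimoto similarity distributions, and mean pairwise Euclidean
    property distances, together with a curation pipeline for SMILES/SDF input
    and a synthetic-library generator with known chemotype ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    ChemmineR,
    ChemmineOB,
    ggplot2,
    rlang
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    vegan,
    withr
Config/testthat/edition: 3
biocViews: Cheminformatics, DataImport, Visualization
RoxygenNote: 7.3.3
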