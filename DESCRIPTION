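Package: strucnet
Title: Weighted Structural Brain Network Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Construction and group-level analysis of weighted structural
    brain connectomes on an 82-region cortical/subcortical parcellation.
    Builds connectivity matrices from streamline summaries with length and
    volume correction, computes the weighted nodal and global graph metrics
    used in clinical connectomics (strength, nodal/global/local efficiency,
    weighted clustering, betweenness, vulnerability, characteristic path
    length), estimates small-worldness against degree-matched random
    networks, performs permutation inference for general linear models with
    covariates and max-statistic family-wise error correction, implements
    the network-based statistic for connected components of altered edges,
    identifies betweenness hubs, computes fMRI laterality indices, and
    simulates synthetic connectome cohorts with planted group effects for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
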