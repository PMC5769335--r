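Package: EnsembleClust
Title: Diverse Cluster Ensembles with Consensus Selection and Significance Testing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for class discovery by diverse cluster ensembles. Generates
    clusterings across multiple algorithms, distance metrics, cluster sizes and
    80% observation subsamples; completes unsampled assignments by k-nearest
    neighbour majority voting; combines the array into consensus partitions by
    majority voting, k-modes, the cluster-based similarity partitioning
    algorithm (CSPA) and link-based cluster ensembles (LCE); selects the
    cluster number by the proportion of ambiguous clustering (PAC); evaluates
    partitions with thirteen internal validity indices and external indices
    against reference labels; trims and weights algorithms by rank aggregation
    of index scores; and tests cluster significance against a single Gaussian
    null with a Monte Carlo cluster-index test.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    cluster,
    class,
    clue,
    e1071,
    kernlab,
    mclust,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
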