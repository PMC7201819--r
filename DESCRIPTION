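Package: mieaclust
Title: Fuzzy Clustering with a Modified Immune Evolutionary Algorithm
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fuzzy c-means clustering of numeric tabular data driven by a
    modified immune evolutionary algorithm (MIEA): a real-valued genetic
    algorithm over cluster-center chromosomes augmented with adaptive
    vaccine extraction, vaccination, and immune selection, which guards
    the search against the local minima that plain alternating
    optimization can fall into. Includes the fuzzy c-means machinery
    (membership updates with the degenerate zero-distance case, objective
    and fitness transforms, chunked map/reduce-style objective
    evaluation), Relief feature weighting with repeated-run averaging and
    threshold or bottom-k pruning, external cluster validation (clustering
    F-measure and majority-mapping accuracy), a labeled Gaussian-mixture
    simulator for fully reproducible experiments, and a small command-line
    interface composing simulate, weight, cluster, and evaluate stages.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    e1071,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
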