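Package: degent
Title: Degree-Based Graph Entropy Descriptors for QSPR Modelling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Computes the k-th degree-based graph entropy of
    hydrogen-suppressed molecular graphs, with emphasis on the
    second-degree-based entropy whose normalizer is the first Zagreb
    index, alongside a suite of classical degree-based topological
    indices (Zagreb, forgotten, inverse sum indeg, symmetric division
    degree, sum connectivity, reciprocal Randic). Provides exact
    enumeration of alkane constitutional isomers (trees with bounded
    maximum degree) via canonical tree codes, simple-OLS
    structure-property regression with the full QSPR report
    (coefficient uncertainties, R squared, residual standard error,
    F statistic and its significance), correlation tables, bundled
    benchmark datasets for octane isomers, benzenoid hydrocarbons and
    drug-related compounds, and reproduction reports checking computed
    descriptors and fits against the reference values shipped with
    those datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    igraph
Suggests:
    ChemmineR,
    ChemmineOB,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
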