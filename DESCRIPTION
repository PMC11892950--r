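Package: gmendr
Title: Gene-Informed Microbial-Enzyme Decomposition Modelling and
    Cellulose-Decomposer Community Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools linking cellulose-decomposer community data to soil-carbon
    dynamics: community-level genomic trait indices (rrn copy number,
    abundance-weighted genome size and GC content), functional-gene microarray
    preprocessing and log response-ratio analysis, community dissimilarity,
    ordination, dispersion, stochasticity-ratio and matrix-correlation
    statistics, random-matrix-theory thresholded co-occurrence networks with
    per-sample sub-network topology, and a microbial-enzyme decomposition
    (MEND-family) soil-carbon model with Shuffled Complex Evolution
    calibration and Critical Objective Function Index uncertainty
    quantification, optionally informed by cellulose-decomposing gene
    abundances. A synthetic-data module generates every input the pipeline
    consumes so all stages are testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    vegan,
    igraph,
    lhs,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
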