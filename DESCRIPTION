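Package: raidr
Title: Virtual DNA Microarray for In Vitro to In Vivo Extrapolation of
    Transcriptome Responses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds and applies a bank of per-gene weighted elastic-net
    models (a "virtual microarray") that predict in vivo liver gene
    expression fold changes from chemical structure descriptors and in
    vitro hepatocyte transcriptome data. Includes the reliability-based
    fold-change adjustment rules, sample weighting, gene filtering, and
    descriptor curation/normalization used to prepare toxicogenomics
    training data; PCA-based read-across analytics (loading lengths,
    quadrant gene rankings, principal-component gene sets, biosimilar
    neighbor retrieval); quantitative IVIVE evaluation by normalized
    per-gene RMSE with Welch's t-test; a minimal PLS-DA; and a synthetic
    data generator that emulates paired in vivo/in vitro replicate
    designs with MAS5-style detection calls.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    nortest,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
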