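Package: aflpmask
Title: Replicate-Based Masking and Quality Evaluation of AFLP Character
    Matrices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Automated reduction of AFLP (amplified fragment length
    polymorphism) presence/absence character matrices based on marker
    reproducibility among replicated profiles of single individuals.
    Classifies replicate pairs into nine per-bin states, computes bin and
    replicate reliability criteria and two replicate mismatch error rates
    (Bonin and Jaccard), iteratively masks unreliable bins and replicates
    to a fixpoint, and sweeps a grid of reliability thresholds to emit
    candidate masked matrices. A companion evaluation suite scores
    candidate matrices with Nei-Li and uncorrected binary distances,
    neighbor-joining trees, nonparametric bootstrap resolution scores,
    stemminess, and the variance captured by the leading axes of a
    principal coordinate analysis. Includes readers for two
    genotyping-table dialects, NEXUS/text matrix writers, a synthetic
    data generator with known per-bin error rates, and a command-line
    front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    grDevices,
    graphics,
    stats,
    utils
Suggests:
    optparse,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
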