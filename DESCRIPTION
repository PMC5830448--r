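Package: mendelscreen
Title: Family-Based Screening for Heritable DNA Methylation Marks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects heritable (Mendelian-like) DNA methylation marks in
    multiplex families. Fits, per CpG probe, a two-component Gaussian
    mixture model and a pedigree-coupled "Mendelian" variant of it in which
    group membership is the carrier status of a rare autosomal variant,
    both by (generalized) EM with fixed mixing weights. The difference in
    maximized log-likelihoods (delta-l) ranks probes by how Mendelian their
    M-values are over and above how bimodal they are. Includes exact
    segregation-analysis carrier priors under a single-founder-origin
    model, posterior carrier probabilities for typed and untyped family
    members, Cox proportional-hazards likelihood-ratio association testing
    of carrier probabilities with disease, SNP-proximity trend validation,
    and a synthetic multi-generational cohort simulator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    purrr,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
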