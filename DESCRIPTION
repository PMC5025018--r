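Package: unifracx
Title: Expanded UniFrac Dissimilarities and Rarefaction-Stability
    Diagnostics for Microbiome Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes phylogenetic beta-diversity between microbiome
    samples with four UniFrac weightings (unweighted, weighted,
    information and ratio) plus the Bray-Curtis dissimilarity, from a
    Newick tree and an OTU count table.  Includes seeded rarefaction,
    rare-OTU filtering, Bayesian-multiplicative zero replacement,
    principal coordinates analysis with Procrustes overlay, and a
    rarefaction-instance stability diagnostic (per-sample relative PC1
    deviation) with confidence-ellipse summaries.  Synthetic generators
    (monoculture communities, uniform single-site communities with
    uneven sequencing depth, two-group communities, long-branch
    rarefaction-flip instances) reproduce the behaviours each metric is
    known for without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    phangorn,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vegan,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
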