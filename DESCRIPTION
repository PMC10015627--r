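Package: phyloregime
Title: Phylogenetic Comparative Analysis of Genome Size, Transposable
    Elements and Gene-Family Turnover Across Reproductive Modes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying how reproductive mode (selfing versus
    outcrossing) shapes genome evolution on a phylogeny. Implements
    two-state Mk models with AICc selection and marginal ancestral states
    to paint selfer/outcrosser regimes onto branches; restricted
    maximum-likelihood Brownian-motion reconstruction of ancestral genome
    sizes with confidence intervals; Hansen-type Ornstein-Uhlenbeck
    adaptation models with regime-specific primary optima, phylogenetic
    half-life and stationary variance; birth-death gene-family turnover
    estimation with Monte-Carlo significance, Storey q-values, ancestral
    count reconstruction and parallel gain/loss classification; and a
    seeded synthetic-data generator so the whole pipeline is testable
    without external genome data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    withr,
    phytools,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
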