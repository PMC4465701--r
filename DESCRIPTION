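Package: commphy
Title: Community Phylogenetic Structure and Trait Convergence in Metacommunities
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing the phylogenetic and functional structure of
    presence/absence metacommunities sampled along environmental and spatial
    gradients. Implements node-count phylogenetic distances, net relatedness
    (NRI) and nearest taxon (NTI) indices with tip-label randomization nulls
    drawn from per-site regional species pools, phylogenetic fuzzy-weighting
    (matrix P) with principal coordinates of phylogenetic structure (PCPS) and
    db-RDA axis selection, community-weighted trait matrices with matrix
    correlation tests of trait convergence and phylogenetic niche conservatism
    (rho(TE), rho(PT), partial rho(TE.P) with a d-separation verdict), and
    two-set variation partitioning of structure indices against habitat and
    latitude. A synthetic metacommunity generator with clade-structured
    latitudinal ranges, Brownian-motion traits and a tunable habitat filter
    provides ground-truthed data for calibration and power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    stats,
    utils,
    vegan
Suggests:
    jsonlite,
    picante,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
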