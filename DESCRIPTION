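Package: founderkin
Title: Time-Resolved Kinship, MRCA and IBD Analysis of Founder-Population Genealogies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing ascending genealogies of founder populations
    such as colonial-era Quebec. Computes pedigree kinship and inbreeding
    coefficients at maximal genealogical depth, assigns ancestors to 25-year
    periods (with marriage-year imputation) and tracks per-group mean kinship
    and inbreeding trajectories, performs classical multidimensional scaling
    of pairwise kinship distances per period, enumerates most recent common
    ancestors (MRCAs) of proband pairs with genetic-contribution weighting and
    bootstrap-averaged cumulative curves, and links pedigree structure to
    identity-by-descent segment sharing through a gene-dropping simulator with
    Haldane recombination. A configurable synthetic-genealogy generator
    emulates founder immigration waves, regional endogamy and
    bottleneck-then-expansion demography so that every analysis stage can be
    exercised without access-restricted registry data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
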