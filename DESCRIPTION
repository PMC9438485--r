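Package: hzclines
Title: Hybrid-Zone Genomic Clines, Sex-Linked Marker Behavior, and
    Windowed Divergence for ZW Systems
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing hybrid zones between divergent lineages in
    ZW sex-determination systems genotyped with reduced-representation
    sequencing tags. Classifies markers by population-genetic behavior into
    W-behaving and Z-behaving categories (including neo-sex chromosomes),
    computes per-SNP Weir-Cockerham differentiation and tag-based sliding
    window divergence and diversity (DXY, pi), builds permutation null
    distributions, estimates maximum-likelihood hybrid indices, fits
    per-locus genomic clines with permutation tests against the neutral
    admixture expectation, calls non-recombining divergent-block haplotypes,
    and bundles a synthetic hybrid-zone generator with known truth for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
LinkingTo:
    Rcpp
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
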