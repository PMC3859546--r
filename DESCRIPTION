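Package: ovismthap
Title: Sheep Mitochondrial DNA Haplogroup and Demographic History Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for the population-genetic analysis of sheep (Ovis aries
    and wild Ovis gmelinii) mitochondrial DNA. Classifies control-region
    sequences into the five domestic sheep haplogroups (A-E) from diagnostic
    nucleotide positions anchored to the AF010406 reference, parses the
    75/76 bp tandem-repeat units that mark the two maternal clusters,
    and computes haplotype and nucleotide diversity, between-group
    divergence (Dxy), Tajima's D and Fu's Fs neutrality tests with
    coalescent p-values, mismatch distributions with sudden-expansion model
    fitting and a parametric-bootstrap goodness-of-fit test, multivariate
    spatial autocorrelation of haplogroup composition over distance classes,
    Tamura-Nei neighbor-joining trees with bootstrap support, and
    median-joining haplotype networks. Includes a seeded synthetic-data
    generator (haplogroup-structured panels, coalescent samples under
    constant-size and sudden-expansion demographies, spatial panels with
    haplogroup-frequency clines) so the complete pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    geosphere,
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
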