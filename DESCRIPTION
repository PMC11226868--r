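Package: bsrmap
Title: Bulked Segregant RNA-Seq Mapping and CAPS Genotyping for a Dominant Plant Locus
Version: 0.1.0
Authors@R:
    person("bsrmap", "developers", email = "bsrmap@example.org", role = c("aut", "cre"))
Description: Simulation-backed pipeline for map-based cloning of a single
    dominant plant locus from an F2 cross. Implements delta(SNP-index)
    bulked segregant analysis with Monte-Carlo null confidence envelopes
    and a sliding-window genome scan; in-silico restriction digestion and
    CAPS (cleaved amplified polymorphic sequence) marker design and
    genotype calling; recombinant screening and candidate-interval
    delimitation on fine-mapping marker tables; segregation chi-square
    tests; and exact genotype-phenotype association tests on germplasm
    panels. A seeded synthetic-data generator produces F2 populations,
    pooled bulk read counts, marker tables, and germplasm panels with the
    statistical structure the analysis assumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    Biostrings,
    BiocGenerics
Suggests:
    testthat (>= 3.0.0),
    withr,
    VariantAnnotation,
    GenomeInfoDb,
    SummarizedExperiment,
    S4Vectors
Config/testthat/edition: 3
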