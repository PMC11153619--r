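Package: poolsex
Title: Sex-Linked Region Discovery from Pooled Sequencing of Sexed Individuals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects sex-determining regions from two-pool ("pool-sex")
    whole-genome sequencing of phenotypically sexed individuals. Screens a
    two-sample VCF for the XY (or ZW) allele-balance signature -- heterozygous
    in the heterogametic pool, homozygous in the homogametic pool -- clusters
    candidate variants by genomic distance and ranks clusters genome-wide;
    detects Y-hemizygous sequence from modal-normalized per-base coverage of
    the two pools; intersects per-species male-specific SNPs from deep
    amplicon panels across taxa; and simulates pooled sequencing data with a
    planted sex-determining region and Y-specific insertion so every stage is
    verifiable against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    data.table,
    vcfR,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    igraph,
    jsonlite,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
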