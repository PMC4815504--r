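Package: radzw
Title: Sex-Linked Marker Discovery from RAD-Seq Data Under ZW Sex
    Determination
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers sex-linked RAD-seq markers under an explicit ZW (or
    mirrored XY) chromosomal sex-determination model, combining marker
    presence-absence between sexes, read-depth evidence of hemizygosity,
    SNP segregation patterns and genotypic linkage disequilibrium.
    Includes catalogue-level coverage filters and per-individual depth
    normalization, classification of hermaphrodites into monogenic (WW)
    and amphigenic (ZW) karyotypes, a genotypic LD permutation test with
    a Genepop-format exporter, Weir-Cockerham F(ST) and polymorphism
    summaries, restriction-site density arithmetic for sex-linked region
    size estimation, and a forward simulator of dioecious and
    androdioecious (selfing) populations used to validate every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
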