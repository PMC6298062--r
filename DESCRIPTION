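Package: pedagg
Title: Familial Aggregation Tests and Benchmarking on Large Pedigrees
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detection of familial aggregation of binary traits in large and
    unstructured pedigrees. Implements the genealogical index of familiality
    (IF), kinship sum (KS), kinship group ratio (GR), kinship group closest
    relative (GC) and binomial (PB) tests with Monte-Carlo empirical null
    distributions obtained by resampling affected labels across families,
    Benjamini-Hochberg adjustment, family-level summarization and
    tie-averaged ranking. Includes a Mendelian autosomal-dominant trait
    simulator (gene dropping with penetrance and generation masking,
    prevalence-matched Bernoulli controls), a synthetic multi-family pedigree
    generator, and a case-family-detection benchmark producing rank
    summaries, top-rank overlap tables and precision/recall curves.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
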