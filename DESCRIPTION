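Package: genorules
Title: Rule-Based Screening of Single-Sample Genotypes for Deterministic Traits
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Screens single-sample genotype files (VCF or delimited genotype
    tables) against user-written deterministic trait rules. Rules are expressed
    either in a small script dialect (sequential if-blocks over genotype
    equality tests, assigning a numeric risk and a text comment) or in a
    structured plaintext language built from Any/All condition blocks, which is
    transpiled to the script dialect. Designed for mono- and oligogenic trait
    screening (carrier status, dietary tolerances, pathway variants) where the
    phenotype follows deterministically from genotypes at a few loci, not for
    polygenic risk scoring. Includes a synthetic fixture generator so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    vcfR,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    yaml,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
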