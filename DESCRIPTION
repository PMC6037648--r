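Package: gh57csr
Title: Conserved Sequence Region Fingerprinting of the Alpha-Amylase Family GH57
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Detects the five conserved sequence regions (CSRs) of glycoside
    hydrolase family GH57 proteins by position-specific profile scanning,
    extracts the 36-position sequence fingerprint, classifies sequences into
    enzyme-specificity and "like"-protein groups from their catalytic
    machinery and diagnostic fingerprint positions, computes sequence-logo
    frequency and information-content matrices, and builds bootstrapped
    neighbor-joining trees from concatenated CSRs. Ships a synthetic-data
    generator that emulates the statistical structure of the family so the
    whole pipeline is testable without database downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
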