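Package: boolrules
Title: Complexity and Classification of Boolean Regulatory Logic
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing the logical update rules of Boolean network
    models of gene regulation. Represents Boolean functions as truth tables and
    expression trees; classifies them into biologically meaningful types
    (effective, unate, canalyzing, nested canalyzing, read-once); computes
    Boolean complexity via Quine-McCluskey minimization with algebraic
    factoring and an exact small-k search; computes average sensitivity through
    hypercube edge counting; constructs minimum-sensitivity functions from
    Hart's edge-maximizing good sets; and runs census, enrichment and
    network-sensitivity statistics over the full function space and over
    collections of network models.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
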