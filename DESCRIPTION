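Package: phanticodon
Title: Phage tRNA Anticodon-Nuclease Sensitivity Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Comparative analysis of phage-encoded tRNAs against their bacterial
    host's tRNA repertoire. Locates the anticodon arm (5-bp stem, 7-nt loop)
    in tRNA gene sequences, classifies loop mutations at the cleavage sites of
    host anticodon nucleases (VapC, PrrC, RelE, colicins and relatives) from a
    user-editable target catalog, quantifies isoacceptor prevalence and
    avoidance across a phage collection, and tests the codon-compensation
    alternative hypothesis with cusp-style codon usage tables, preferred-codon
    concordance, and Welch and paired t-tests. Ships a seeded synthetic-data
    generator that plants host/phage tRNA fixtures and coding-sequence sets
    with known ground truth, so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
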