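Package: venomcomp
Title: Compositional Analysis of Venom-Gland Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing bulk venom-gland transcriptomes between
    venom phenotypes, treating transcript abundances (TPM) as compositional
    data. Implements coverage-based transcript presence calling, multiplicative
    zero replacement and the centered log-ratio (clr) transform, a pairwise
    expression-divergence test against an empirical null built from nontoxin
    transcripts, toxin-family composition summaries, and rank-sum comparison
    of per-individual toxin counts. Ships the printed expression, presence and
    sample tables of a nine-individual Mojave rattlesnake study as plain-text
    fixtures, and a synthetic-data generator that emulates the two-venom-type
    structure for calibration and power checks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
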