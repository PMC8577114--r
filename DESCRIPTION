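Package: cleavemap
Title: Cleavage-Site Mapping from Semi-Tryptic Peptides in Label-Free Degradomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Locates protease cleavage sites from label-free quantitative
    proteomics of active-versus-inactive enzyme digests. Peptides from a
    semi-tryptic search are mapped onto their parent protein, classified as
    fully tryptic or semi-tryptic, compared between conditions with a scaled
    fold-change convention for one-condition peptides, and scored with a
    per-class z statistic on log2 ratios; significant semi-tryptic termini are
    collapsed into deduplicated scissile-bond calls (Schechter-Berger P1-P1')
    with merged modification-form evidence, spanning-peptide cross-checks and
    domain annotation. Also provides in-silico tryptic digestion, motif and
    N-glycosylation sequon scans, ProtParam-style extinction coefficients and
    average masses, isoform coordinate mapping, alignment identity, and a
    seeded synthetic-experiment generator for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
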