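Package: strmatch
Title: Comparison and Authentication of Short Tandem Repeat Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: High-throughput pairwise comparison of short tandem repeat (STR)
    genotype profiles for authentication of human cell lines and
    patient-derived xenograft models. Computes the Tanabe (Sorensen-Dice) and
    both Masters similarity scores over per-marker allele sets, flags
    potential sample mixing (three or more alleles at three or more loci),
    produces ranked batch reports, generates seeded synthetic profiles for
    testing, and queries the Cellosaurus CLASTR STR similarity service.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    httr2,
    jsonlite,
    readr,
    readxl,
    stats,
    tibble,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
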