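Package: fhhscreen
Title: Family Health History Extraction and Hereditary-Cancer Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Rule-based extraction of family health history (FHH) from the
    combined structured fields and free-text comments of the dedicated FHH
    section of an electronic health record. Structured values are marked
    inside the concatenated text, entities (family members, cancers, cancer
    syndromes, gene mutations, age of onset) are recognized with editable
    lexicons, conflicts between structured and comment-derived mentions are
    reconciled with a fixed set of heuristics, and family member-condition
    and family member-onset relations are linked and normalized. A criteria
    engine evaluates the normalized assertions against NCCN family-history
    criteria for genetic testing of hereditary breast/ovarian and colorectal
    cancers, in a structured-only or NLP-augmented mode and under two
    uncertainty policies. Includes a synthetic-corpus generator with gold
    annotations, relation-level and patient-level scoring with bootstrap
    confidence intervals, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    purrr,
    rlang,
    stringr,
    tibble,
    tidyr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
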