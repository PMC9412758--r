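test_that("lexicon matching finds the worked example entities", {
  marked <- combine_fields(worked_entry())
  ents <- match_lexicon(marked)
  expect_setequal(
    paste(ents$label, ents$surface),
    c("CANCER CANCER", "BREAST Breast", "FAMILYMEMBER great-aunt",
      "ONSET_AGE dx at age of 52", "FAMILYMEMBER AUNT"))
  expect_equal(ents$norm[ents$label == "FAMILYMEMBER" & !ents$is_structural],
               "GREAT_AUNT")
})

test_that("syndromes, genes and empty segments match as expected", {
  lynch <- extract_entities(combine_fields(
    entry1("CANCER, COLON", "AUNT", NA, "Lynch syndrome")))
  expect_true(any(lynch$label == "SYNDROME" & lynch$norm == "LYNCH"))
  gene <- extract_entities(combine_fields(
    entry1(NA, "SISTER", NA, "BRCA1 positive")))
  expect_true(any(gene$label == "GENE_MUT" & gene$norm == "BRCA1"))
  none <- extract_entities(combine_fields(
    entry1("DIABETES", NA, NA, "no relevant history")))
  expect_equal(nrow(none), 0)
})

test_that("an empty lexicon is a configuration error", {
  cfg <- fhh_config()
  cfg$lexicon$conditions <- cfg$lexicon$conditions[0, ]
  expect_error(match_lexicon(combine_fields(worked_entry()), cfg),
               class = "fhh_config_error")
})

test_that("context rules ignore excluded mentions and flag uncertainty", {
  ents <- extract_entities(combine_fields(
    entry1("CANCER, BREAST", "MOTHER", 52, "live with her daughter")))
  daughter <- ents[ents$norm == "DAUGHTER", ]
  expect_equal(daughter$status, "IGNORED")

  unc <- extract_entities(combine_fields(
    entry1("CANCER", "FATHER", NA, "possible, colon cancer")))
  colon <- unc[unc$label == "COLON", ]
  expect_true(all(colon$uncertainty))

  structural <- extract_entities(combine_fields(worked_entry()))
  aunt <- structural[structural$surface == "AUNT", ]
  expect_true(aunt$is_structural)
})

test_that("classification fills code, sex and side", {
  ents <- extract_entities(combine_fields(
    entry1("CANCER, BREAST", NA, 40, "paternal aunt")))
  fm <- ents[ents$label == "FAMILYMEMBER", ]
  expect_equal(fm$side, "PATERNAL")
  expect_equal(fm$sex, "FEMALE")
  expect_equal(degree_of(fm$code), 2L)

  bro <- extract_entities(combine_fields(
    entry1("CANCER, COLON", NA, 50, "brother")))
  expect_equal(bro$sex[bro$label == "FAMILYMEMBER"], "MALE")
})

test_that("onset parsing covers the four subtypes and decade bounds", {
  expect_equal(parse_onset("52")[c("kind", "lower", "upper")],
               list(kind = "AGE", lower = 52, upper = 52))
  expect_equal(parse_onset("in his 30s")[c("kind", "lower", "upper")],
               list(kind = "RANGE", lower = 30, upper = 39))
  expect_equal(parse_onset("late 50s")[c("kind", "lower", "upper")],
               list(kind = "RANGE", lower = 55, upper = 59))
  expect_equal(parse_onset("early 40s")[c("kind", "lower", "upper")],
               list(kind = "RANGE", lower = 40, upper = 44))
  expect_equal(parse_onset("in 1965")$kind, "PERIOD")
  expect_equal(parse_onset("postmenstruation")$kind, "STRING")
})

test_that("multiplicity parsing handles prefixes, words and zero", {
  expect_equal(parse_multiplicity("2× sisters"), 2L)
  expect_equal(parse_multiplicity("2 x sisters"), 2L)
  expect_equal(parse_multiplicity("x3 aunts"), 3L)
  expect_equal(parse_multiplicity("three aunts"), 3L)
  expect_equal(parse_multiplicity("sister"), 1L)
  expect_warning(m <- parse_multiplicity("0x sisters"))
  expect_equal(m, 1L)
})

test_that("extraction is deterministic and non-overlapping per label", {
  corpus <- small_corpus(30, seed = 9)
  for (i in seq_len(min(nrow(corpus$entries), 60))) {
    marked <- combine_fields(corpus$entries[i, ])
    a <- extract_entities(marked)
    b <- extract_entities(marked)
    expect_identical(a, b)
    expect_no_error(validate_entities(a, marked))
  }
})
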