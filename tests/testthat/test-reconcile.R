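reconciled <- function(cond, rel, onset, comment) {
  entry <- entry1(cond, rel, onset, comment)
  marked <- combine_fields(entry)
  ents <- extract_entities(marked)
  ents <- override_condition(ents, marked)
  reconcile(ents, marked)
}

status_of <- function(ents, pick) {
  ents$status[which(pick(ents))][1]
}

test_that("a colorectal syndrome in the comment overrides coded colon", {
  e <- reconciled("CANCER, COLON", "FATHER", NA, "Lynch syndrome")
  expect_equal(status_of(e, \(x) x$norm == "LYNCH"), "ACTIVE")
  expect_equal(status_of(e, \(x) x$norm == "COLON"), "IGNORED")
})

test_that("a comment onset range overrides the structured age", {
  e <- reconciled("CANCER, BREAST", "MOTHER", 50, "The late 50s")
  expect_equal(status_of(e, \(x) x$label == "ONSET_RANGE"), "ACTIVE")
  expect_equal(status_of(e, \(x) x$is_structural & x$label == "ONSET_AGE"),
               "IGNORED")
  rng <- e[e$label == "ONSET_RANGE", ]
  expect_equal(c(rng$onset_lower, rng$onset_upper), c(55, 59))
})

test_that("period and string onsets lose to a structured age", {
  p <- reconciled("CANCER, BREAST", "MOTHER", 50, "In 1985")
  expect_equal(status_of(p, \(x) x$label == "ONSET_PERIOD"), "IGNORED")
  expect_equal(status_of(p, \(x) x$is_structural & x$label == "ONSET_AGE"),
               "ACTIVE")
  s <- reconciled("CANCER, BREAST", "MOTHER", 50, "10 years ago")
  expect_equal(status_of(s, \(x) x$label == "ONSET_STRING"), "IGNORED")
  expect_equal(status_of(s, \(x) x$is_structural & x$label == "ONSET_AGE"),
               "ACTIVE")
})

test_that("a deceased age with no structured onset infers a range", {
  e <- reconciled("CANCER, BREAST", "MOTHER", NA,
                  "Deceased at age 60 years")
  inferred <- e[e$label == "ONSET_RANGE" & e$status == "ACTIVE", ]
  expect_equal(nrow(inferred), 1)
  expect_equal(c(inferred$onset_lower, inferred$onset_upper), c(0, 60))
  expect_true(inferred$inferred)
  expect_equal(status_of(e, \(x) x$label == "DECEASED_AGE"), "IGNORED")
})

test_that("a specific comment relative replaces the structured one", {
  e <- reconciled("CANCER", "AUNT", NA, "Great-aunt")
  expect_equal(status_of(e, \(x) x$norm == "GREAT_AUNT"), "ACTIVE")
  expect_equal(status_of(e, \(x) x$is_structural & x$norm == "AUNT"),
               "IGNORED")
})

test_that("a conjunction keeps relatives from both fields", {
  e <- reconciled("CANCER, BREAST", "MOTHER", NA, "And grandmother")
  expect_equal(status_of(e, \(x) x$norm == "GRANDMOTHER"), "ACTIVE")
  expect_equal(status_of(e, \(x) x$norm == "MOTHER"), "ACTIVE")
})

test_that("a side-only phrase decorates the structured relative", {
  e <- reconciled("CANCER, OVARIAN", "AUNT", 50, "Father side")
  aunt <- e[e$norm == "AUNT" & e$is_structural, ]
  expect_equal(aunt$status, "ACTIVE")
  expect_equal(aunt$side, "PATERNAL")
  expect_equal(status_of(e, \(x) x$code == "SIDE_ONLY"), "IGNORED")
})

test_that("multiplicity expands into that many relative instances", {
  e <- reconciled("CANCER, BREAST", NA, 42, "2× sisters")
  sis <- e[e$norm == "SISTER" & e$status == "ACTIVE", ]
  expect_equal(nrow(sis), 2)
  expect_equal(sort(sis$instance), 1:2)
})

test_that("override terms cancel the coded condition", {
  e <- reconciled("CANCER, BREAST", "MOTHER", NA, "precancer, age 30")
  expect_equal(status_of(e, \(x) x$norm == "BREAST"), "IGNORED")
  none <- reconciled("CANCER, BREAST", "MOTHER", 40, "dx at 40")
  expect_equal(status_of(none, \(x) x$norm == "BREAST"), "ACTIVE")
})

test_that("reconciliation is idempotent and creates no condition entities", {
  corpus <- small_corpus(40, seed = 13)
  for (i in seq_len(min(nrow(corpus$entries), 80))) {
    entry <- corpus$entries[i, ]
    marked <- combine_fields(entry)
    ents <- override_condition(extract_entities(marked), marked)
    once <- reconcile(ents, marked)
    twice <- reconcile(once, marked)
    expect_identical(as.data.frame(twice), as.data.frame(once))
    is_cond <- function(x) sum(x$class %in% c("CANCER", "SYNDROME",
                                              "GENE_MUT"))
    expect_equal(is_cond(once), is_cond(ents))
  }
})

test_that("at most one onset stays active per relative scope", {
  corpus <- small_corpus(40, seed = 17)
  anns <- annotate_entries(corpus$entries)
  for (a in anns) {
    act <- a$entities[a$entities$status == "ACTIVE" &
                        a$entities$class == "ONSET", ]
    per_seg <- table(act$seg_id)
    expect_true(all(per_seg <= 1))
  }
})
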