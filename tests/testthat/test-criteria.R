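test_that("relevance filtering keeps cancer-related entries only", {
  entries <- dplyr::bind_rows(
    entry1("CANCER", "AUNT", NA, "", eid = "E1"),
    entry1("DIABETES", "MOTHER", NA, "insulin dependent", eid = "E2"),
    entry1("OTHER", "AUNT", NA, "Lynch syndrome", eid = "E3"))
  kept <- filter_relevant_entries(entries)
  expect_setequal(kept$entry_id, c("E1", "E3"))
})

test_that("degrees of relationship follow consanguinity", {
  expect_equal(degree_of("MOTHER"), 1L)
  expect_equal(degree_of("AUNT"), 2L)
  expect_equal(degree_of("GREAT_AUNT"), 3L)
  expect_true(is.na(degree_of("NOT_A_RELATIVE")))
})

test_that("side resolution prefers explicit features over code defaults", {
  cfg <- fhh_config()
  expect_equal(side_of(make_assertion("MATERNAL_GRANDMOTHER", "BREAST")),
               "MATERNAL")
  expect_equal(side_of(make_assertion("AUNT", "BREAST",
                                      side = "PATERNAL")), "PATERNAL")
  expect_equal(side_of(make_assertion("SISTER", "BREAST")), "BOTH")
  expect_equal(side_of(make_assertion("AUNT", "BREAST")), "UNKNOWN")
})

test_that("a second-degree breast cancer in the 30s qualifies", {
  a <- make_assertion("AUNT", "BREAST", onset_kind = "RANGE",
                      onset_lower = 30, onset_upper = 39, sex = "FEMALE")
  res <- evaluate_breast_ovarian(profile1(), a)
  expect_true(res$eligible)
  expect_equal(res$matched_criteria[[1]], "BO1")
  # a range straddling the threshold qualifies optimistically, not strictly
  b <- make_assertion("AUNT", "BREAST", onset_kind = "RANGE",
                      onset_lower = 40, onset_upper = 49, sex = "FEMALE")
  expect_true(evaluate_breast_ovarian(profile1(), b)$eligible)
  strict <- fhh_config(range_threshold_policy = "STRICT")
  expect_false(evaluate_breast_ovarian(profile1(), b, strict)$eligible)
})

test_that("no assertions means not eligible", {
  res <- evaluate_breast_ovarian(profile1(), make_assertion("AUNT", "X")[0, ])
  expect_false(res$eligible)
  expect_equal(length(res$matched_criteria[[1]]), 0)
})

test_that("three same-side breast/prostate relatives fire only BO5", {
  a <- dplyr::bind_rows(
    make_assertion("PATERNAL_AUNT", "BREAST", sex = "FEMALE",
                   onset_kind = "AGE", onset_lower = 60, onset_upper = 60),
    make_assertion("PATERNAL_UNCLE", "PROSTATE", sex = "MALE",
                   onset_kind = "AGE", onset_lower = 65, onset_upper = 65),
    make_assertion("PATERNAL_GRANDMOTHER", "BREAST", sex = "FEMALE",
                   onset_kind = "AGE", onset_lower = 70, onset_upper = 70))
  res <- evaluate_breast_ovarian(profile1(), a)
  expect_equal(res$matched_criteria[[1]], "BO5")
  # opposite sides never tally together
  b <- a
  b$side <- c("PATERNAL", "MATERNAL", "UNKNOWN")
  expect_false(evaluate_breast_ovarian(profile1(), b)$eligible)
})

test_that("ashkenazi ancestry gates the any-breast/prostate criterion", {
  a <- make_assertion("GREAT_AUNT", "BREAST", sex = "FEMALE",
                      onset_kind = "AGE", onset_lower = 70,
                      onset_upper = 70)
  expect_false(evaluate_breast_ovarian(profile1(ashkenazi = NA), a)$eligible)
  expect_false(evaluate_breast_ovarian(profile1(ashkenazi = FALSE),
                                       a)$eligible)
  res <- evaluate_breast_ovarian(profile1(ashkenazi = TRUE), a)
  expect_equal(res$matched_criteria[[1]], "BO6")
})

test_that("colorectal criteria fire on their canonical cases", {
  c2 <- evaluate_colorectal(profile1(), make_assertion(
    "FATHER", "COLON", sex = "MALE", side = "PATERNAL",
    onset_kind = "AGE", onset_lower = 45, onset_upper = 45))
  expect_equal(c2$matched_criteria[[1]], "C2")

  c1 <- evaluate_colorectal(profile1(), make_assertion(
    "AUNT", "LYNCH", condition_class = "SYNDROME"))
  expect_equal(c1$matched_criteria[[1]], "C1")

  late <- evaluate_colorectal(profile1(), make_assertion(
    "MOTHER", "ENDOMETRIAL", sex = "FEMALE", side = "MATERNAL",
    onset_kind = "AGE", onset_lower = 55, onset_upper = 55))
  expect_false(late$eligible)
})

test_that("rectal cancer counts as colon only under the wide definition", {
  a <- make_assertion("MOTHER", "RECTAL", sex = "FEMALE", side = "MATERNAL",
                      onset_kind = "AGE", onset_lower = 45,
                      onset_upper = 45)
  expect_true(evaluate_colorectal(profile1(), a)$eligible)
  narrow <- fhh_config(colon_definition = "COLON")
  expect_false(evaluate_colorectal(profile1(), a, narrow)$eligible)
})

test_that("screening modes diverge when evidence lives in the comment", {
  prof <- structure(list(patient_id = "P1", age = 40, sex = "FEMALE",
                         ashkenazi_jewish = NA, entries = worked_entry()),
                    class = "fhh_patient")
  res_s <- screen_patient(prof, "STRUCTURED_ONLY")
  res_n <- screen_patient(prof, "NLP_AUGMENTED")
  expect_false(any(res_s$eligible))
  expect_false(any(res_n$eligible))

  prof2 <- structure(list(patient_id = "P2", age = 40, sex = "FEMALE",
                          ashkenazi_jewish = NA,
                          entries = entry1("CANCER", "AUNT", NA,
                                           "breast ca, dx in 30s",
                                           pid = "P2")),
                     class = "fhh_patient")
  s2 <- screen_patient(prof2, "STRUCTURED_ONLY")
  n2 <- screen_patient(prof2, "NLP_AUGMENTED")
  expect_false(any(s2$eligible))
  bo <- n2[n2$cohort == "BREAST_OVARIAN", ]
  expect_true(bo$eligible)
  expect_equal(bo$matched_criteria[[1]], "BO1")
})

test_that("adding assertions never removes matched criteria", {
  base <- random_assertions(6, seed = 31)
  extra <- random_assertions(4, seed = 32)
  for (cohort in c("BREAST_OVARIAN", "COLORECTAL")) {
    eval_fn <- if (cohort == "BREAST_OVARIAN") evaluate_breast_ovarian
               else evaluate_colorectal
    before <- eval_fn(profile1(), base)$matched_criteria[[1]]
    after <- eval_fn(profile1(),
                     dplyr::bind_rows(base, extra))$matched_criteria[[1]]
    expect_true(all(before %in% after))
  }
})

test_that("the engine agrees with the exhaustive criteria oracle", {
  configs <- list(
    fhh_config(),
    fhh_config(uncertainty_policy = "EXCLUDE"),
    fhh_config(range_threshold_policy = "STRICT"),
    fhh_config(colon_definition = "COLON", unknown_side_counts = TRUE),
    fhh_config(comment_polyposis = FALSE,
               inferred_range_participates = FALSE))
  for (seed in 1:25) {
    a <- random_assertions(sample(0:10, 1), seed = seed)
    cfg <- configs[[(seed %% length(configs)) + 1]]
    aj <- c(TRUE, FALSE, NA)[(seed %% 3) + 1]
    prof <- profile1(ashkenazi = aj)
    bo <- evaluate_breast_ovarian(prof, a, cfg)
    expect_equal(sort(bo$matched_criteria[[1]]),
                 oracle_criteria("BREAST_OVARIAN", a, aj, cfg),
                 info = paste("seed", seed))
    crc <- evaluate_colorectal(prof, a, cfg)
    expect_equal(sort(crc$matched_criteria[[1]]),
                 oracle_criteria("COLORECTAL", a, aj, cfg),
                 info = paste("seed", seed))
  }
})

test_that("including uncertain assertions can only widen the eligible set", {
  corpus <- small_corpus(80, seed = 41)
  profiles <- patient_profiles(corpus$entries, corpus$patients)
  inc <- screen_patients(profiles, "NLP_AUGMENTED", fhh_config())
  exc <- screen_patients(profiles, "NLP_AUGMENTED",
                         fhh_config(uncertainty_policy = "EXCLUDE"))
  j <- dplyr::inner_join(
    inc |> dplyr::select("patient_id", "cohort", inc = "eligible"),
    exc |> dplyr::select("patient_id", "cohort", exc = "eligible"),
    by = c("patient_id", "cohort"))
  expect_true(all(!j$exc | j$inc))
  expect_gte(sum(j$inc), sum(j$exc))
})

test_that("augmentation only adds eligibility on supplement-only corpora", {
  phen <- c(structured_only = 0.4, supplement_site = 0.3,
            supplement_onset = 0.3)
  corpus <- generate_corpus(sim_params(n_patients = 80, seed = 43,
                                       phenomena = phen))
  profiles <- patient_profiles(corpus$entries, corpus$patients)
  aug <- screen_patients(profiles, "NLP_AUGMENTED")
  str_ <- screen_patients(profiles, "STRUCTURED_ONLY")
  j <- dplyr::inner_join(
    aug |> dplyr::select("patient_id", "cohort", aug = "eligible"),
    str_ |> dplyr::select("patient_id", "cohort", str = "eligible"),
    by = c("patient_id", "cohort"))
  expect_true(all(!j$str | j$aug))
})
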