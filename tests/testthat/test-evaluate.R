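test_that("metric arithmetic handles perfect, disjoint and empty cases", {
  ann <- annotate_entry(worked_entry())
  keys <- relation_keys(list(ann))
  perfect <- score_relations(keys, keys)$by_type
  expect_true(all(perfect$precision == 1 & perfect$recall == 1 &
                    perfect$f1 == 1))

  other <- keys
  other$target_norm <- "OVARIAN"
  disjoint <- score_relations(keys, other)$by_type
  micro <- disjoint[disjoint$relation == "micro", ]
  expect_equal(micro$precision, 0)
  expect_equal(micro$recall, 0)

  m <- metrics_from_counts(0, 0, 0)
  expect_true(is.na(m$precision) && is.na(m$recall) && is.na(m$f1))
})

test_that("true positives require matching features, not just spans", {
  ann <- annotate_entry(worked_entry())
  keys <- relation_keys(list(ann))
  flipped <- keys
  flipped$uncertain[flipped$type == "FX_CANCER"] <- TRUE
  scored <- score_relations(flipped, keys)$by_type
  cancer <- scored[scored$relation == "FX_CANCER", ]
  expect_equal(cancer$tp, 0)
  expect_equal(cancer$fp, 1)
  expect_equal(cancer$fn, 1)
})

test_that("micro-averages equal metrics from summed confusion counts", {
  corpus <- small_corpus(50, seed = 51)
  pert <- perturb_typos(corpus, 0.4, seed = 7)
  scored <- score_relations(
    relation_keys(annotate_entries(pert$entries)), pert$gold_relations)
  tab <- scored$by_type
  micro <- tab[tab$relation == "micro", ]
  by_type <- tab[tab$relation != "micro", ]
  recomputed <- micro_average(by_type)
  expect_equal(micro$precision, recomputed$precision)
  expect_equal(micro$recall, recomputed$recall)
  expect_equal(micro$f1, recomputed$f1)
  expect_equal(micro$tp, sum(by_type$tp))
})

test_that("bootstrap intervals behave on constant and ordinary corpora", {
  const <- tibble::tibble(entry_id = sprintf("E%d", 1:20),
                          type = "FX_CANCER", tp = 2L, fp = 1L, fn = 0L)
  ci <- bootstrap_ci(const, metric = "precision", B = 200, seed = 3)
  expect_true(ci$available)
  expect_equal(ci$lower, ci$upper)
  expect_equal(ci$lower, 2 / 3)

  corpus <- small_corpus(50, seed = 53)
  pert <- perturb_typos(corpus, 0.4, seed = 9)
  scored <- score_relations(
    relation_keys(annotate_entries(pert$entries)), pert$gold_relations)
  point <- scored$by_type$f1[scored$by_type$relation == "micro"]
  ci2 <- bootstrap_ci(scored$per_entry, metric = "f1", B = 1000, seed = 5)
  expect_true(ci2$available)
  expect_lte(ci2$lower, point)
  expect_gte(ci2$upper, point)
  ci3 <- bootstrap_ci(scored$per_entry, metric = "f1", B = 1000, seed = 5)
  expect_identical(ci2, ci3)
})

test_that("sparse relation types yield an unavailable interval", {
  sparse <- tibble::tibble(entry_id = "E1", type = "FX_SYNDROME",
                           tp = 1L, fp = 0L, fn = 1L)
  ci <- bootstrap_ci(sparse, metric = "recall", B = 100, seed = 1)
  expect_false(ci$available)
  expect_true(is.na(ci$lower))
  expect_error(bootstrap_ci(sparse, metric = "recall", B = 0),
               class = "fhh_param_error")
})

test_that("interval endpoints are monotone in the coverage level", {
  corpus <- small_corpus(40, seed = 57)
  pert <- perturb_typos(corpus, 0.5, seed = 11)
  scored <- score_relations(
    relation_keys(annotate_entries(pert$entries)), pert$gold_relations)
  ci80 <- bootstrap_ci(scored$per_entry, "f1", B = 400, level = 0.8,
                       seed = 13)
  ci95 <- bootstrap_ci(scored$per_entry, "f1", B = 400, level = 0.95,
                       seed = 13)
  expect_lte(ci95$lower, ci80$lower)
  expect_gte(ci95$upper, ci80$upper)
})

test_that("algorithm comparison scores both modes against gold", {
  gold <- tibble::tibble(
    patient_id = rep(sprintf("P%d", 1:6), each = 2),
    cohort = rep(c("BREAST_OVARIAN", "COLORECTAL"), 6),
    eligible = rep(c(TRUE, FALSE, TRUE, FALSE, FALSE, TRUE), each = 2))
  both <- compare_algorithms(gold, gold, gold, B = 50, seed = 1)
  expect_true(all(both$precision == 1))
  expect_true(all(both$recall == 1))

  none <- gold
  none$eligible <- FALSE
  cmp <- compare_algorithms(none, gold, gold, B = 50, seed = 1)
  expect_equal(cmp$recall[cmp$mode == "STRUCTURED_ONLY"], 0)
  expect_true(is.na(cmp$precision[cmp$mode == "STRUCTURED_ONLY"]))
  expect_equal(cmp$recall[cmp$mode == "NLP_AUGMENTED"], 1)

  short <- gold[gold$patient_id != "P1", ]
  expect_error(compare_algorithms(short, gold, gold),
               class = "fhh_alignment_error")
  expect_error(compare_algorithms(short, gold, gold), "P1")
})

test_that("structured mode has zero recall when evidence lives in comments", {
  phen <- c(supplement_site = 0.5, multiplicity = 0.25, gene = 0.25)
  corpus <- generate_corpus(sim_params(n_patients = 40, seed = 61,
                                       phenomena = phen,
                                       p_eligible_bo = 0.5,
                                       p_eligible_crc = 0))
  # keep only entries whose eligibility evidence is comment-borne
  keep <- corpus$entries$phenomenon %in% c("multiplicity", "gene")
  entries <- corpus$entries[keep, ]
  profiles <- patient_profiles(entries, corpus$patients)
  str_ <- screen_patients(profiles, "STRUCTURED_ONLY")
  aug <- screen_patients(profiles, "NLP_AUGMENTED")
  gold <- dplyr::bind_rows(lapply(profiles, function(pr) {
    a <- corpus$gold_assertions[
      corpus$gold_assertions$patient_id == pr$patient_id &
        corpus$gold_assertions$entry_id %in% entries$entry_id, ]
    dplyr::bind_rows(evaluate_breast_ovarian(pr, a),
                     evaluate_colorectal(pr, a))
  }))
  expect_gt(sum(gold$eligible), 0)
  cmp <- compare_algorithms(
    str_ |> dplyr::select("patient_id", "cohort", "eligible"),
    aug |> dplyr::select("patient_id", "cohort", "eligible"),
    gold |> dplyr::select("patient_id", "cohort", "eligible"),
    B = 100, seed = 3)
  expect_equal(cmp$recall[cmp$mode == "STRUCTURED_ONLY"], 0)
  expect_gte(cmp$recall[cmp$mode == "NLP_AUGMENTED"],
             cmp$recall[cmp$mode == "STRUCTURED_ONLY"])
})
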