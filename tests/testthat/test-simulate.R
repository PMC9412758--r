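test_that("parameter validation rejects impossible settings", {
  expect_error(sim_params(n_patients = 0), class = "fhh_param_error")
  expect_error(sim_params(phenomena = c(structured_only = 0.5)),
               class = "fhh_param_error")
  expect_error(sim_params(p_eligible_bo = 1.2), class = "fhh_param_error")
  expect_error(sim_params(phenomena = c(irrelevant = 1),
                          p_eligible_bo = 1),
               class = "fhh_param_error")
})

test_that("generation is deterministic under a fixed seed", {
  a <- generate_corpus(sim_params(n_patients = 30, seed = 7))
  b <- generate_corpus(sim_params(n_patients = 30, seed = 7))
  expect_identical(a$entries, b$entries)
  expect_identical(a$gold_relations, b$gold_relations)
  expect_identical(a$gold_eligibility, b$gold_eligibility)
  c_ <- generate_corpus(sim_params(n_patients = 30, seed = 8))
  expect_false(identical(a$entries$comment, c_$entries$comment))
})

test_that("the corpus has the requested size and complete gold", {
  corpus <- generate_corpus(sim_params(n_patients = 100, seed = 7))
  expect_equal(nrow(corpus$patients), 100)
  expect_equal(nrow(corpus$gold_eligibility), 200)
  expect_setequal(unique(corpus$gold_eligibility$cohort),
                  c("BREAST_OVARIAN", "COLORECTAL"))
  expect_true(all(corpus$entries$patient_id %in%
                    corpus$patients$patient_id))
})

test_that("designated eligibility is reflected in the gold labels", {
  corpus <- generate_corpus(sim_params(n_patients = 120, seed = 19,
                                       p_eligible_bo = 0.3,
                                       p_eligible_crc = 0.2))
  gold <- corpus$gold_eligibility
  bo_rate <- mean(gold$eligible[gold$cohort == "BREAST_OVARIAN"])
  crc_rate <- mean(gold$eligible[gold$cohort == "COLORECTAL"])
  # designated proportions are floors; chance qualification adds more
  expect_gte(bo_rate, 0.15)
  expect_gte(crc_rate, 0.1)
})

test_that("phenomenon frequencies are multinomial around the request", {
  params <- sim_params(n_patients = 1000, seed = 29, p_eligible_bo = 0,
                       p_eligible_crc = 0)
  corpus <- generate_corpus(params)
  free <- corpus$entries[!corpus$entries$injected, ]
  n <- nrow(free)
  expect_gte(n, 1500)
  obs <- table(factor(free$phenomenon, levels = names(params$phenomena)))
  for (ph in names(params$phenomena)) {
    p <- params$phenomena[[ph]]
    expect_lt(abs(obs[[ph]] - n * p), 3 * sqrt(n * p * (1 - p)) + 1e-9)
  }
})

test_that("typo perturbation is seeded, rate-bounded and gold-preserving", {
  corpus <- generate_corpus(sim_params(n_patients = 80, seed = 31))
  same <- perturb_typos(corpus, 0, seed = 5)
  expect_identical(same$entries$comment, corpus$entries$comment)
  pert <- perturb_typos(corpus, 0.5, seed = 5)
  pert2 <- perturb_typos(corpus, 0.5, seed = 5)
  expect_identical(pert$entries, pert2$entries)
  expect_gt(sum(pert$entries$typo), 0)
  expect_identical(pert$gold_relations, corpus$gold_relations)
})

test_that("typos can only lower recall on condition relations", {
  corpus <- generate_corpus(sim_params(n_patients = 80, seed = 37))
  pert <- perturb_typos(corpus, 0.6, seed = 6)
  clean <- score_relations(relation_keys(annotate_entries(corpus$entries)),
                           corpus$gold_relations)
  noisy <- score_relations(relation_keys(annotate_entries(pert$entries)),
                           pert$gold_relations)
  micro <- function(s) s$by_type$recall[s$by_type$relation == "micro"]
  expect_lte(micro(noisy), micro(clean))
  expect_lt(micro(noisy), 1)
})

test_that("corpus files round-trip through the writers", {
  corpus <- generate_corpus(sim_params(n_patients = 10, seed = 41))
  prefix <- file.path(withr::local_tempdir(), "corpus")
  paths <- write_corpus(corpus, prefix)
  entries <- read_fhh_table(paths[["entries"]])
  expect_equal(nrow(entries), nrow(corpus$entries))
  gold <- read_eligibility(paths[["gold_eligibility"]])
  expect_equal(sum(gold$eligible), sum(corpus$gold_eligibility$eligible))
})
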