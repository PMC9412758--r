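bo_gene_set <- c("BRCA1", "BRCA2", "BRCA1/2", "CHEK2", "ATM", "PALB2",
                 "TP53", "PTEN", "CDH1")
bo_syndrome_set <- c("COWDEN", "LI_FRAUMENI")
crc_gene_set <- c("MLH1", "MSH2", "PMS2", "MSH6", "EPCAM", "MYH", "MUTYH")
crc_syndrome_set <- c("LYNCH", "HNPCC", "FAP", "APC", "SERRATED_POLYPOSIS",
                      "POLYPOSIS")
c4_cancer_set <- c("COLON", "ENDOMETRIAL", "OVARIAN", "STOMACH",
                   "SMALL_INTESTINE", "KIDNEY", "URETERAL", "BLADDER",
                   "URETHRAL", "BRAIN", "PANCREAS")

colon_set <- function(config) {
  if (config$colon_definition == "COLON_RECTAL") c("COLON", "RECTAL")
  else "COLON"
}

#' Filter FHH entries relevant to familial cancer risk
#'
#' Keeps entries whose coded condition is cancer/syndrome/gene-related or
#' whose comment matches the condition lexicons; everything else (diabetes,
#' hypertension, ...) is dropped before screening.
#'
#' @param entries an `fhh_entries` tibble
#' @param config an [fhh_config()]
#' @return the filtered `fhh_entries`
#' @export
filter_relevant_entries <- function(entries, config = fhh_config()) {
  if (nrow(entries) == 0) return(entries)
  lex <- config$lexicon
  cond_pat <- paste(
    vapply(lex$conditions$term, term_pattern, character(1)),
    collapse = "|")
  keep <- vapply(seq_len(nrow(entries)), function(i) {
    code_hit <- lookup_condition_code(entries$condition_code[i], lex)
    if (!is.null(code_hit) && isTRUE(code_hit$relevant)) return(TRUE)
    com <- entries$comment[i]
    nzchar(com) && str_detect(str_to_lower(com),
                              regex(cond_pat, ignore_case = TRUE))
  }, logical(1))
  entries[keep, ]
}

#' Degree of relationship for a relative code
#'
#' Parent/sibling/child are first degree; grandparent/aunt/uncle/niece/
#' nephew/half-sibling/grandchild second; great-grandparent/great-aunt/
#' great-uncle/cousin third. Unknown codes give `NA`.
#'
#' @param relative_code normalized relative code(s)
#' @param config an [fhh_config()]
#' @return integer degree(s), `NA` for unknown codes
#' @export
degree_of <- function(relative_code, config = fhh_config()) {
  tab <- config$lexicon$relative_codes
  key <- gsub(" ", "_", normalize_code(relative_code))
  tab$degree[match(key, tab$code)]
}

#' Side of the family for an assertion
#'
#' An explicit side feature (from a side cue or a sided code such as
#' MATERNAL_GRANDMOTHER) wins; the father is paternal and the mother
#' maternal; full siblings and the patient's descendants belong to both
#' sides; otherwise unknown.
#'
#' @param assertion a single assertion row (or tibble; vectorized)
#' @param config an [fhh_config()]
#' @return character side(s): MATERNAL, PATERNAL, BOTH or UNKNOWN
#' @export
side_of <- function(assertion, config = fhh_config()) {
  tab <- config$lexicon$relative_codes
  code_side <- tab$side[match(assertion$relative_code, tab$code)]
  out <- assertion$side
  out[is.na(out)] <- "UNKNOWN"
  use_code <- out == "UNKNOWN" & !is.na(code_side)
  out[use_code] <- code_side[use_code]
  out
}

onset_meets <- function(assertions, threshold, config) {
  kind <- assertions$onset_kind
  lower <- assertions$onset_lower
  upper <- assertions$onset_upper
  ok <- rep(FALSE, nrow(assertions))
  age <- !is.na(kind) & kind == "AGE"
  ok[age] <- lower[age] <= threshold
  rng <- !is.na(kind) & kind == "RANGE"
  if (config$range_threshold_policy == "OPTIMISTIC") {
    ok[rng] <- lower[rng] <= threshold
  } else {
    ok[rng] <- upper[rng] <= threshold
  }
  if (!config$inferred_range_participates) {
    ok[rng & assertions$onset_inferred] <- FALSE
  }
  ok
}

prepare_assertions <- function(assertions, config) {
  if (nrow(assertions) == 0) return(assertions)
  if (config$uncertainty_policy == "EXCLUDE") {
    assertions <- assertions[!assertions$uncertain, ]
  }
  if (nrow(assertions) == 0) return(assertions)
  assertions$degree <- ifelse(is.na(assertions$degree),
                              degree_of(assertions$relative_code, config),
                              assertions$degree)
  assertions$side <- side_of(assertions, config)
  assertions
}

side_count <- function(assertions, rows, config) {
  a <- assertions[rows, ]
  tally <- function(sides) {
    keep <- a$side %in% sides |
      (config$unknown_side_counts & a$side == "UNKNOWN")
    sum(a$count[keep])
  }
  max(tally(c("MATERNAL", "BOTH")), tally(c("PATERNAL", "BOTH")))
}

eligibility_row <- function(patient_id, cohort, matched, supporting,
                            config, mode = NA_character_) {
  tibble(
    patient_id = patient_id, cohort = cohort,
    eligible = length(matched) > 0,
    matched_criteria = list(matched),
    supporting = list(supporting),
    mode = mode, uncertainty_policy = config$uncertainty_policy)
}

#' Evaluate the breast/ovarian genetic-testing criteria
#'
#' Family-history criteria for hereditary breast or ovarian cancer:
#' * BO1 first- or second-degree relative with breast cancer at age <= 45
#' * BO2 first- or second-degree relative with ovarian cancer
#' * BO3 first-degree relative with pancreatic cancer
#' * BO4 breast cancer in a male relative (any degree)
#' * BO5 three or more relation-counted first/second-degree relatives with
#'   breast or prostate cancer on the same side of the family
#' * BO6 Ashkenazi Jewish ancestry and any breast or prostate cancer in any
#'   relative at any age
#' * BO7 BRCA1/2, CHEK2, ATM, PALB2, TP53, PTEN or CDH1, or Cowden or
#'   Li-Fraumeni syndrome, in any relative
#'
#' A patient is eligible when at least one criterion matches.
#'
#' @param profile a patient profile (list with `patient_id`,
#'   `ashkenazi_jewish`, ...)
#' @param assertions an assertion tibble for this patient
#' @param config an [fhh_config()]
#' @return a one-row eligibility tibble
#' @export
evaluate_breast_ovarian <- function(profile, assertions,
                                    config = fhh_config()) {
  a <- prepare_assertions(assertions, config)
  matched <- character(0)
  supporting <- integer(0)
  add <- function(id, rows) {
    if (length(rows) > 0 && any(rows)) {
      matched <<- c(matched, id)
      supporting <<- union(supporting, which(rows))
    }
  }
  if (nrow(a) > 0) {
    deg12 <- !is.na(a$degree) & a$degree %in% 1:2
    add("BO1", a$condition == "BREAST" & deg12 & onset_meets(a, 45, config))
    add("BO2", a$condition == "OVARIAN" & deg12)
    add("BO3", a$condition == "PANCREAS" & !is.na(a$degree) & a$degree == 1)
    add("BO4", a$condition == "BREAST" & a$sex == "MALE")
    bo5_rows <- a$condition %in% c("BREAST", "PROSTATE") & deg12
    if (side_count(a, bo5_rows, config) >= 3) add("BO5", bo5_rows)
    if (isTRUE(profile$ashkenazi_jewish)) {
      add("BO6", a$condition %in% c("BREAST", "PROSTATE"))
    }
    add("BO7", (a$condition_class == "GENE_MUT" &
                  a$condition %in% bo_gene_set) |
               (a$condition_class == "SYNDROME" &
                  a$condition %in% bo_syndrome_set))
  }
  eligibility_row(profile$patient_id, "BREAST_OVARIAN", matched,
                  supporting, config)
}

#' Evaluate the colorectal genetic-testing criteria
#'
#' Family-history criteria for hereditary colorectal cancer:
#' * C1 MLH1, MSH2, PMS2, MSH6, EPCAM, MYH or MUTYH, or Lynch syndrome,
#'   FAP, APC, serrated polyposis or polyposis, in any relative
#' * C2 first-degree relative with colon cancer at age <= 50
#' * C3 first-degree relative with endometrial cancer at age <= 50
#' * C4 three or more relation-counted first/second-degree relatives on the
#'   same side with Lynch syndrome/HNPCC or a cancer of the colon,
#'   endometrium/uterus, ovary, stomach, small bowel, kidney, ureter,
#'   bladder, urethra, brain or pancreas
#'
#' @inheritParams evaluate_breast_ovarian
#' @return a one-row eligibility tibble
#' @export
evaluate_colorectal <- function(profile, assertions,
                                config = fhh_config()) {
  a <- prepare_assertions(assertions, config)
  matched <- character(0)
  supporting <- integer(0)
  add <- function(id, rows) {
    if (length(rows) > 0 && any(rows)) {
      matched <<- c(matched, id)
      supporting <<- union(supporting, which(rows))
    }
  }
  if (nrow(a) > 0) {
    colon <- colon_set(config)
    deg1 <- !is.na(a$degree) & a$degree == 1
    deg12 <- !is.na(a$degree) & a$degree %in% 1:2
    c1_syn <- a$condition_class == "SYNDROME" &
      a$condition %in% crc_syndrome_set
    if (!config$comment_polyposis) {
      c1_syn <- c1_syn & a$condition_source == "structured"
    }
    add("C1", (a$condition_class == "GENE_MUT" &
                 a$condition %in% crc_gene_set) | c1_syn)
    add("C2", a$condition %in% colon & deg1 & onset_meets(a, 50, config))
    add("C3", a$condition == "ENDOMETRIAL" & deg1 &
          onset_meets(a, 50, config))
    c4_set <- union(c4_cancer_set, colon)
    c4_rows <- deg12 & ((a$condition_class == "CANCER" &
                           a$condition %in% c4_set) |
                        (a$condition_class == "SYNDROME" &
                           a$condition %in% c("LYNCH", "HNPCC")))
    if (side_count(a, c4_rows, config) >= 3) add("C4", c4_rows)
  }
  eligibility_row(profile$patient_id, "COLORECTAL", matched, supporting,
                  config)
}

#' Assertions from structured fields alone
#'
#' The structured-data baseline: each relevant entry with both a coded
#' condition and a coded relative yields one assertion; the comment is
#' ignored entirely. The coded age of onset becomes an exact-age onset.
#'
#' @param entries an `fhh_entries` tibble
#' @param config an [fhh_config()]
#' @return an assertion tibble
#' @export
structured_assertions <- function(entries, config = fhh_config()) {
  lex <- config$lexicon
  rows <- map_dfr(seq_len(nrow(entries)), function(i) {
    chit <- lookup_condition_code(entries$condition_code[i], lex)
    rhit <- lookup_relative_code(entries$relative_code[i], lex)
    if (is.null(chit) || chit$class == "OTHER" || is.null(rhit)) return(NULL)
    age <- entries$onset_age[i]
    tibble(
      patient_id = entries$patient_id[i], entry_id = entries$entry_id[i],
      relative_code = rhit$code, degree = rhit$degree, side = rhit$side,
      sex = rhit$sex, condition = chit$norm, condition_class = chit$class,
      onset_kind = if (is.na(age)) NA_character_ else "AGE",
      onset_lower = as.numeric(age), onset_upper = as.numeric(age),
      onset_raw = if (is.na(age)) NA_character_ else as.character(age),
      onset_inferred = FALSE, uncertain = FALSE, count = 1L,
      relative_source = "structured", condition_source = "structured",
      onset_source = if (is.na(age)) NA_character_ else "structured")
  })
  if (nrow(rows) == 0) empty_assertions() else rows
}

#' Screen one patient against both cohorts
#'
#' `STRUCTURED_ONLY` builds assertions from the structured fields alone;
#' `NLP_AUGMENTED` runs the full extraction pipeline over each entry first
#' and feeds the normalized output to the same criteria engine. Entries not
#' relevant to familial cancer risk are filtered out in both modes.
#'
#' @param profile a patient profile from [patient_profiles()]
#' @param mode `"STRUCTURED_ONLY"` or `"NLP_AUGMENTED"`
#' @param config an [fhh_config()]
#' @return a two-row eligibility tibble (one row per cohort)
#' @export
screen_patient <- function(profile,
                           mode = c("NLP_AUGMENTED", "STRUCTURED_ONLY"),
                           config = fhh_config()) {
  mode <- match.arg(mode)
  entries <- filter_relevant_entries(profile$entries, config)
  assertions <- if (mode == "STRUCTURED_ONLY") {
    structured_assertions(entries, config)
  } else {
    extract_assertions(entries, config)
  }
  out <- bind_rows(
    evaluate_breast_ovarian(profile, assertions, config),
    evaluate_colorectal(profile, assertions, config))
  out$mode <- mode
  out
}

#' Screen a set of patients
#'
#' @param profiles list of patient profiles
#' @param mode screening mode, as in [screen_patient()]
#' @param config an [fhh_config()]
#' @return an eligibility tibble, two rows per patient
#' @export
screen_patients <- function(profiles,
                            mode = c("NLP_AUGMENTED", "STRUCTURED_ONLY"),
                            config = fhh_config()) {
  mode <- match.arg(mode)
  bind_rows(lapply(profiles, screen_patient, mode = mode, config = config))
}

#' Write eligibility results as line-delimited records
#'
#' @param results eligibility tibble from [screen_patients()]
#' @param path output path (JSON lines)
#' @return `path`, invisibly
#' @export
write_eligibility <- function(results, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_len(nrow(results))) {
    rec <- list(
      patient_id = results$patient_id[i], cohort = results$cohort[i],
      eligible = results$eligible[i],
      matched_criteria = results$matched_criteria[[i]],
      mode = results$mode[i],
      uncertainty_policy = results$uncertainty_policy[i])
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE), con)
  }
  invisible(path)
}

#' Read eligibility records written by [write_eligibility()]
#'
#' @param path path to a JSON-lines eligibility file
#' @return an eligibility tibble
#' @export
read_eligibility <- function(path) {
  lines <- readLines(path)
  map_dfr(lines, function(l) {
    rec <- jsonlite::fromJSON(l)
    tibble(patient_id = rec$patient_id, cohort = rec$cohort,
           eligible = rec$eligible,
           matched_criteria = list(unlist(rec$matched_criteria) %||%
                                     character(0)),
           mode = rec$mode %||% NA_character_,
           uncertainty_policy = rec$uncertainty_policy %||% NA_character_)
  })
}
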