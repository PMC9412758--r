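#' Simulation parameters
#'
#' Defines the study conditions the synthetic corpus emulates: short
#' telegraphic comments that supplement or correct the structured fields of
#' an FHH entry. `phenomena` gives the relative frequency of each comment
#' phenomenon; entries draw their phenomenon independently, so observed
#' frequencies are multinomial around these proportions. `p_eligible_bo` /
#' `p_eligible_crc` are the proportions of patients for whom one entry is
#' forced to satisfy a criterion of the corresponding cohort (injected
#' entries are flagged and excluded from frequency accounting); free entries
#' may make further patients eligible by chance.
#'
#' @param n_patients number of patients (>= 1)
#' @param mean_entries mean FHH entries per patient (min 1)
#' @param max_entries cap on entries per patient
#' @param phenomena named numeric vector of phenomenon proportions (must sum
#'   to 1); names must be a subset of [sim_phenomena()]
#' @param p_eligible_bo,p_eligible_crc designated-eligible proportions
#' @param p_ashkenazi proportion of patients with Ashkenazi Jewish ancestry
#' @param typo_rate character-level typo rate applied to comment condition
#'   terms (see [perturb_typos()])
#' @param seed integer seed
#' @return a list of class `fhh_sim_params`
#' @export
sim_params <- function(n_patients = 100,
                       mean_entries = 2,
                       max_entries = 5,
                       phenomena = NULL,
                       p_eligible_bo = 0.15,
                       p_eligible_crc = 0.10,
                       p_ashkenazi = 0.02,
                       typo_rate = 0,
                       seed = 42) {
  default_phenomena <- c(
    structured_only = 0.25, supplement_site = 0.12, supplement_onset = 0.12,
    relative_correction = 0.08, conjunction = 0.05, side_only = 0.05,
    multiplicity = 0.05, uncertainty = 0.06, condition_override = 0.04,
    syndrome_override = 0.04, deceased = 0.05, gene = 0.03,
    irrelevant = 0.04, exclusion_context = 0.02)
  phenomena <- phenomena %||% default_phenomena
  if (n_patients < 1) {
    abort("n_patients must be >= 1", class = "fhh_param_error")
  }
  if (any(phenomena < 0) || abs(sum(phenomena) - 1) > 1e-8) {
    abort("phenomenon proportions must be non-negative and sum to 1",
          class = "fhh_param_error")
  }
  if (!all(names(phenomena) %in% sim_phenomena())) {
    abort("unknown phenomenon name", class = "fhh_param_error")
  }
  probs <- c(p_eligible_bo, p_eligible_crc, p_ashkenazi, typo_rate)
  if (any(probs < 0 | probs > 1)) {
    abort("proportions must be in [0, 1]", class = "fhh_param_error")
  }
  qualifying <- setdiff(names(phenomena)[phenomena > 0],
                        c("irrelevant", "condition_override"))
  if ((p_eligible_bo > 0 || p_eligible_crc > 0) && length(qualifying) == 0) {
    abort(paste0("eligible patients requested but no phenomenon that can ",
                 "express a qualifying entry has positive probability"),
          class = "fhh_param_error")
  }
  structure(list(
    n_patients = as.integer(n_patients), mean_entries = mean_entries,
    max_entries = as.integer(max_entries), phenomena = phenomena,
    p_eligible_bo = p_eligible_bo, p_eligible_crc = p_eligible_crc,
    p_ashkenazi = p_ashkenazi, typo_rate = typo_rate,
    seed = as.integer(seed)), class = "fhh_sim_params")
}

#' Comment phenomena the generator can emulate
#'
#' @return character vector of phenomenon names
#' @export
sim_phenomena <- function() {
  c("structured_only", "supplement_site", "supplement_onset",
    "relative_correction", "conjunction", "side_only", "multiplicity",
    "uncertainty", "condition_override", "syndrome_override", "deceased",
    "gene", "irrelevant", "exclusion_context")
}

# ---- instantiation pools ---------------------------------------------------

sim_relatives <- c("MOTHER", "FATHER", "SISTER", "BROTHER", "AUNT", "UNCLE",
                   "GRANDMOTHER", "GRANDFATHER", "MATERNAL_GRANDMOTHER",
                   "PATERNAL_GRANDMOTHER", "DAUGHTER", "SON", "NIECE",
                   "NEPHEW", "COUSIN")
sim_sites <- c("BREAST", "OVARIAN", "COLON", "PANCREAS", "PROSTATE",
               "STOMACH", "KIDNEY", "BLADDER", "BRAIN", "ENDOMETRIAL",
               "RECTAL", "SMALL_INTESTINE")
female_only_sites <- c("BREAST", "OVARIAN", "ENDOMETRIAL")
male_only_sites <- "PROSTATE"

rel_attrs <- function(code, lex) {
  hit <- lookup_relative_code(code, lex)
  list(code = hit$code, degree = hit$degree, sex = hit$sex, side = hit$side)
}

pick_site_for <- function(sex) {
  pool <- sim_sites
  if (sex == "MALE") pool <- setdiff(pool, female_only_sites)
  if (sex == "FEMALE") pool <- setdiff(pool, male_only_sites)
  if (sex == "UNKNOWN") pool <- setdiff(pool, c(female_only_sites,
                                                male_only_sites))
  sample1(pool)
}

pick_relative_for <- function(site, lex) {
  repeat {
    code <- sample1(sim_relatives)
    fm <- rel_attrs(code, lex)
    if (site %in% female_only_sites && fm$sex != "FEMALE") next
    if (site %in% male_only_sites && fm$sex != "MALE") next
    return(fm)
  }
}

site_word <- function(site) {
  words <- c(BREAST = "breast", OVARIAN = "ovarian", COLON = "colon",
             PANCREAS = "pancreatic", PROSTATE = "prostate",
             STOMACH = "stomach", KIDNEY = "kidney", BLADDER = "bladder",
             BRAIN = "brain", ENDOMETRIAL = "uterine", RECTAL = "rectal",
             SMALL_INTESTINE = "small bowel")
  unname(words[site])
}

# ---- gold construction helpers --------------------------------------------

cond_label <- function(norm, class) {
  if (class == "CANCER") norm else class
}

gold_keys_single <- function(entry_id, fm, cond = NULL, onset = NULL,
                             uncertain = FALSE, n_inst = 1L) {
  rows <- list()
  for (inst in seq_len(n_inst)) {
    if (!is.null(cond)) {
      rows[[length(rows) + 1]] <- fast_tibble(
        entry_id = entry_id,
        type = condition_relation_type[[cond$class]],
        source_code = fm$code, source_instance = inst, side = fm$side,
        target_label = cond_label(cond$norm, cond$class),
        target_norm = cond$norm, uncertain = uncertain)
    }
    if (!is.null(onset)) {
      rows[[length(rows) + 1]] <- fast_tibble(
        entry_id = entry_id, type = "FX_ONSET",
        source_code = fm$code, source_instance = inst, side = fm$side,
        target_label = paste0("ONSET_", onset$kind),
        target_norm = paste0(onset$kind, "[", onset$lower, ",",
                             onset$upper, "]"),
        uncertain = FALSE)
    }
  }
  bind_rows(rows)
}

gold_assert_single <- function(pid, entry_id, fm, cond, onset = NULL,
                               uncertain = FALSE, n_inst = 1L,
                               cond_source = "structured") {
  tibble(
    patient_id = pid, entry_id = entry_id,
    relative_code = fm$code, degree = fm$degree, side = fm$side,
    sex = fm$sex, condition = cond$norm, condition_class = cond$class,
    onset_kind = if (is.null(onset)) NA_character_ else onset$kind,
    onset_lower = if (is.null(onset)) NA_real_ else onset$lower,
    onset_upper = if (is.null(onset)) NA_real_ else onset$upper,
    onset_raw = if (is.null(onset)) NA_character_ else
      as.character(onset$raw %||% onset$lower),
    onset_inferred = if (is.null(onset)) FALSE else
      isTRUE(onset$source == "inferred"),
    uncertain = uncertain, count = as.integer(n_inst),
    relative_source = fm$source %||% "structured",
    condition_source = cond_source,
    onset_source = if (is.null(onset)) NA_character_ else onset$source)
}

age_onset <- function(age, source = "structured", raw = NULL) {
  list(kind = "AGE", lower = age, upper = age, source = source,
       raw = raw %||% as.character(age))
}

# ---- templates -------------------------------------------------------------

# Each template returns list(entry = list of entry fields, gold_rel,
# gold_assert, ambiguous). `qualify` is "none", "bo" or "crc" and pins the
# instantiation to a criterion-satisfying variant.
sim_build_entry <- function(phenomenon, pid, eid, qualify, lex) {
  fm_side <- function(fm, side) { fm$side <- side; fm }
  out <- switch(phenomenon,
    structured_only = {
      if (qualify == "bo") {
        site <- sample1(c("BREAST", "OVARIAN"))
        fm <- rel_attrs(sample1(c("MOTHER", "SISTER")), lex)
        age <- if (site == "BREAST") sample1(30:45) else sample1(40:70)
      } else if (qualify == "crc") {
        site <- "COLON"
        fm <- rel_attrs(sample1(c("MOTHER", "FATHER", "BROTHER")), lex)
        age <- sample1(30:50)
      } else {
        fm <- rel_attrs(sample1(sim_relatives), lex)
        site <- pick_site_for(fm$sex)
        age <- sample1(25:80)
      }
      cond <- list(norm = site, class = "CANCER")
      list(entry = list(condition_code = paste0("CANCER, ",
                                                gsub("_", " ", site)),
                        relative_code = fm$code, onset_age = age,
                        comment = ""),
           gold_rel = gold_keys_single(eid, fm, cond, age_onset(age)),
           gold_assert = gold_assert_single(pid, eid, fm, cond,
                                            age_onset(age)))
    },
    supplement_site = {
      if (qualify == "bo") {
        site <- "BREAST"
        fm <- rel_attrs(sample1(c("MOTHER", "SISTER", "AUNT")), lex)
        age <- sample1(30:45)
      } else if (qualify == "crc") {
        site <- "COLON"
        fm <- rel_attrs(sample1(c("MOTHER", "FATHER")), lex)
        age <- sample1(35:50)
      } else {
        fm <- rel_attrs(sample1(sim_relatives), lex)
        site <- pick_site_for(fm$sex)
        age <- sample1(25:80)
      }
      cond <- list(norm = site, class = "CANCER")
      comment <- sample1(c(site_word(site),
                           paste(site_word(site), "ca"),
                           paste(site_word(site), "cancer")))
      list(entry = list(condition_code = "CANCER", relative_code = fm$code,
                        onset_age = age, comment = comment),
           gold_rel = gold_keys_single(eid, fm, cond, age_onset(age)),
           gold_assert = gold_assert_single(pid, eid, fm, cond,
                                            age_onset(age),
                                            cond_source = "comment"))
    },
    supplement_onset = {
      if (qualify == "bo") {
        site <- "BREAST"
        fm <- rel_attrs(sample1(c("MOTHER", "SISTER", "AUNT")), lex)
        dec <- 30L
      } else if (qualify == "crc") {
        site <- "COLON"
        fm <- rel_attrs(sample1(c("MOTHER", "FATHER")), lex)
        dec <- 40L
      } else {
        fm <- rel_attrs(sample1(sim_relatives), lex)
        site <- pick_site_for(fm$sex)
        dec <- sample1(c(50L, 60L, 70L))
      }
      pron <- if (fm$sex == "FEMALE") "her" else "his"
      style <- sample1(c("plain", "pronoun", "age"))
      if (style == "age") {
        age <- dec + sample1(0:9)
        comment <- paste0("dx at age of ", age)
        onset <- age_onset(age, source = "comment", raw = comment)
      } else {
        comment <- if (style == "pronoun") {
          paste0("dx in ", pron, " ", dec, "s")
        } else paste0("dx in ", dec, "s")
        onset <- list(kind = "RANGE", lower = dec, upper = dec + 9,
                      source = "comment", raw = comment)
      }
      cond <- list(norm = site, class = "CANCER")
      list(entry = list(condition_code = paste0("CANCER, ",
                                                gsub("_", " ", site)),
                        relative_code = fm$code, onset_age = NA_integer_,
                        comment = comment),
           gold_rel = gold_keys_single(eid, fm, cond, onset),
           gold_assert = gold_assert_single(pid, eid, fm, cond, onset))
    },
    relative_correction = {
      if (qualify == "bo") {
        site <- "OVARIAN"
        true_fm <- rel_attrs(sample1(c("MATERNAL_GRANDMOTHER",
                                       "PATERNAL_GRANDMOTHER")), lex)
        age <- sample1(40:70)
      } else if (qualify == "crc") {
        site <- "COLON"
        true_fm <- rel_attrs("BROTHER", lex)
        age <- sample1(35:50)
      } else {
        true_fm <- rel_attrs(sample1(c("GREAT_AUNT", "GREAT_UNCLE",
                                       "MATERNAL_GRANDMOTHER", "COUSIN")),
                             lex)
        site <- pick_site_for(true_fm$sex)
        age <- sample1(51:80)
      }
      coded <- switch(true_fm$code,
                      GREAT_AUNT = "AUNT", GREAT_UNCLE = "UNCLE",
                      MATERNAL_GRANDMOTHER = "GRANDMOTHER",
                      PATERNAL_GRANDMOTHER = "GRANDMOTHER",
                      BROTHER = "SIBLING", COUSIN = "UNCLE")
      term <- str_to_lower(gsub("_", " ", true_fm$code))
      if (true_fm$code == "GREAT_AUNT") term <- "great-aunt"
      if (true_fm$code == "GREAT_UNCLE") term <- "great-uncle"
      true_fm$source <- "comment"
      cond <- list(norm = site, class = "CANCER")
      list(entry = list(condition_code = paste0("CANCER, ",
                                                gsub("_", " ", site)),
                        relative_code = coded, onset_age = age,
                        comment = term),
           gold_rel = gold_keys_single(eid, true_fm, cond, age_onset(age)),
           gold_assert = gold_assert_single(pid, eid, true_fm, cond,
                                            age_onset(age)))
    },
    conjunction = {
      if (qualify == "bo") {
        site <- "OVARIAN"
        fm1 <- rel_attrs("MOTHER", lex)
        fm2 <- rel_attrs("GRANDMOTHER", lex)
        age <- sample1(40:70)
      } else if (qualify == "crc") {
        site <- "COLON"
        fm1 <- rel_attrs("FATHER", lex)
        fm2 <- rel_attrs("UNCLE", lex)
        age <- sample1(35:50)
      } else {
        fm1 <- rel_attrs(sample1(c("AUNT", "UNCLE", "GRANDMOTHER",
                                   "GRANDFATHER")), lex)
        fm2 <- rel_attrs(sample1(c("AUNT", "UNCLE", "GRANDMOTHER",
                                   "GRANDFATHER")), lex)
        site <- pick_site_for(if (fm1$sex == fm2$sex) fm1$sex else "UNKNOWN")
        age <- sample1(51:80)
      }
      fm2$source <- "comment"
      term2 <- str_to_lower(gsub("_", " ", fm2$code))
      conj <- sample1(c("and", "also"))
      cond <- list(norm = site, class = "CANCER")
      list(entry = list(condition_code = paste0("CANCER, ",
                                                gsub("_", " ", site)),
                        relative_code = fm1$code, onset_age = age,
                        comment = paste(conj, term2)),
           gold_rel = bind_rows(
             gold_keys_single(eid, fm1, cond, age_onset(age)),
             gold_keys_single(eid, fm2, cond, age_onset(age))),
           gold_assert = bind_rows(
             gold_assert_single(pid, eid, fm1, cond, age_onset(age)),
             gold_assert_single(pid, eid, fm2, cond, age_onset(age))))
    },
    side_only = {
      if (qualify == "bo") {
        site <- "OVARIAN"
        fm <- rel_attrs("AUNT", lex)
        age <- sample1(40:70)
        cond <- list(norm = site, class = "CANCER")
        code_str <- paste0("CANCER, ", site)
        cond_source <- "structured"
      } else if (qualify == "crc") {
        cond <- list(norm = "LYNCH", class = "SYNDROME")
        fm <- rel_attrs("AUNT", lex)
        age <- NA_integer_
        code_str <- "LYNCH SYNDROME"
        cond_source <- "structured"
      } else {
        fm <- rel_attrs(sample1(c("AUNT", "UNCLE", "GRANDMOTHER",
                                  "GRANDFATHER")), lex)
        site <- pick_site_for(fm$sex)
        age <- sample1(51:80)
        cond <- list(norm = site, class = "CANCER")
        code_str <- paste0("CANCER, ", gsub("_", " ", site))
        cond_source <- "structured"
      }
      side <- sample1(c("PATERNAL", "MATERNAL"))
      phrase <- if (side == "PATERNAL") {
        sample1(c("father side", "father's side", "paternal side"))
      } else {
        sample1(c("mother side", "mother's side", "maternal side"))
      }
      fm <- fm_side(fm, side)
      onset <- if (is.na(age)) NULL else age_onset(age)
      list(entry = list(condition_code = code_str, relative_code = fm$code,
                        onset_age = age, comment = phrase),
           gold_rel = gold_keys_single(eid, fm, cond, onset),
           gold_assert = gold_assert_single(pid, eid, fm, cond, onset,
                                            cond_source = cond_source))
    },
    multiplicity = {
      if (qualify == "bo") {
        site <- "BREAST"
        fm <- rel_attrs("SISTER", lex)
        age <- sample1(30:45)
        n <- 2L
      } else if (qualify == "crc") {
        site <- "COLON"
        fm <- rel_attrs("SISTER", lex)
        age <- sample1(35:50)
        n <- 2L
      } else {
        fm <- rel_attrs(sample1(c("AUNT", "UNCLE", "COUSIN")), lex)
        site <- pick_site_for(fm$sex)
        age <- sample1(51:80)
        n <- sample1(2:3)
      }
      term <- str_to_lower(fm$code)
      style <- sample1(c("times", "word"))
      comment <- if (style == "times") {
        paste0(n, "× ", term, "s")
      } else {
        paste(c("one", "two", "three")[n], paste0(term, "s"))
      }
      fm$source <- "comment"
      cond <- list(norm = site, class = "CANCER")
      list(entry = list(condition_code = paste0("CANCER, ",
                                                gsub("_", " ", site)),
                        relative_code = NA_character_, onset_age = age,
                        comment = comment),
           gold_rel = gold_keys_single(eid, fm, cond, age_onset(age),
                                       n_inst = n),
           gold_assert = gold_assert_single(pid, eid, fm, cond,
                                            age_onset(age), n_inst = n))
    },
    uncertainty = {
      if (qualify == "bo") {
        site <- "OVARIAN"
        fm <- rel_attrs("MOTHER", lex)
        age <- sample1(40:70)
      } else if (qualify == "crc") {
        site <- "COLON"
        fm <- rel_attrs("FATHER", lex)
        age <- sample1(35:50)
      } else {
        fm <- rel_attrs(sample1(sim_relatives), lex)
        site <- pick_site_for(fm$sex)
        age <- sample1(51:80)
      }
      cue <- sample1(c("possible", "probably", "suspected"))
      comment <- paste0(cue, " ", site_word(site), " ca")
      cond <- list(norm = site, class = "CANCER")
      list(entry = list(condition_code = "CANCER", relative_code = fm$code,
                        onset_age = age, comment = comment),
           gold_rel = gold_keys_single(eid, fm, cond, age_onset(age),
                                       uncertain = TRUE),
           gold_assert = gold_assert_single(pid, eid, fm, cond,
                                            age_onset(age),
                                            uncertain = TRUE,
                                            cond_source = "comment"))
    },
    condition_override = {
      fm <- rel_attrs(sample1(sim_relatives), lex)
      site <- pick_site_for(fm$sex)
      variant <- sample1(c("precancer_age", "benign"))
      if (variant == "precancer_age") {
        age <- sample1(25:60)
        comment <- paste0("precancer, age ", age)
        onset <- age_onset(age, source = "comment",
                           raw = paste0("age ", age))
        gold_rel <- gold_keys_single(eid, fm, cond = NULL, onset = onset)
      } else {
        comment <- "benign cyst"
        gold_rel <- gold_keys_single(eid, fm, cond = NULL, onset = NULL)
      }
      list(entry = list(condition_code = paste0("CANCER, ",
                                                gsub("_", " ", site)),
                        relative_code = fm$code, onset_age = NA_integer_,
                        comment = comment),
           gold_rel = gold_rel,
           gold_assert = empty_assertions())
    },
    syndrome_override = {
      fm <- rel_attrs(sample1(sim_relatives), lex)
      age <- sample1(35:70)
      cond <- list(norm = "LYNCH", class = "SYNDROME")
      list(entry = list(condition_code = "CANCER, COLON",
                        relative_code = fm$code, onset_age = age,
                        comment = "Lynch syndrome"),
           gold_rel = gold_keys_single(eid, fm, cond, age_onset(age)),
           gold_assert = gold_assert_single(pid, eid, fm, cond,
                                            age_onset(age),
                                            cond_source = "comment"))
    },
    deceased = {
      if (qualify == "bo") {
        site <- "OVARIAN"
        fm <- rel_attrs("SISTER", lex)
      } else if (qualify == "crc") {
        site <- "COLON"
        fm <- rel_attrs(sample1(c("MOTHER", "FATHER")), lex)
      } else {
        fm <- rel_attrs(sample1(c("AUNT", "UNCLE", "GRANDMOTHER",
                                  "GRANDFATHER")), lex)
        site <- pick_site_for(fm$sex)
      }
      dage <- sample1(55:90)
      comment <- paste0("deceased at age ", dage, " years")
      onset <- list(kind = "RANGE", lower = 0, upper = dage,
                    source = "inferred", raw = comment)
      cond <- list(norm = site, class = "CANCER")
      list(entry = list(condition_code = paste0("CANCER, ",
                                                gsub("_", " ", site)),
                        relative_code = fm$code, onset_age = NA_integer_,
                        comment = comment),
           gold_rel = gold_keys_single(eid, fm, cond, onset),
           gold_assert = gold_assert_single(pid, eid, fm, cond, onset))
    },
    gene = {
      gene <- if (qualify == "crc") sample1(c("MLH1", "MSH2", "MSH6"))
              else if (qualify == "bo") sample1(c("BRCA1", "BRCA2", "CHEK2"))
              else sample1(c("BRCA1", "BRCA2", "MLH1", "PALB2", "CHEK2"))
      fm <- rel_attrs(sample1(sim_relatives), lex)
      cond <- list(norm = gene, class = "GENE_MUT")
      list(entry = list(condition_code = NA_character_,
                        relative_code = fm$code, onset_age = NA_integer_,
                        comment = paste(gene, "positive")),
           gold_rel = gold_keys_single(eid, fm, cond),
           gold_assert = gold_assert_single(pid, eid, fm, cond,
                                            cond_source = "comment"))
    },
    irrelevant = {
      fm <- rel_attrs(sample1(sim_relatives), lex)
      code <- sample1(c("DIABETES", "HYPERTENSION", "ASTHMA", "ARTHRITIS"))
      comment <- sample1(c("insulin dependent", "dietary controlled",
                           "", "mild"))
      list(entry = list(condition_code = code, relative_code = fm$code,
                        onset_age = NA_integer_, comment = comment),
           gold_rel = NULL,
           gold_assert = empty_assertions())
    },
    exclusion_context = {
      fm <- rel_attrs(sample1(c("MOTHER", "AUNT", "GRANDMOTHER")), lex)
      if (qualify == "bo") {
        site <- "BREAST"
        fm <- rel_attrs("MOTHER", lex)
        age <- sample1(30:45)
      } else if (qualify == "crc") {
        site <- "COLON"
        fm <- rel_attrs("MOTHER", lex)
        age <- sample1(35:50)
      } else {
        site <- pick_site_for(fm$sex)
        age <- sample1(51:80)
      }
      cond <- list(norm = site, class = "CANCER")
      list(entry = list(condition_code = paste0("CANCER, ",
                                                gsub("_", " ", site)),
                        relative_code = fm$code, onset_age = age,
                        comment = "lives with her daughter"),
           gold_rel = gold_keys_single(eid, fm, cond, age_onset(age)),
           gold_assert = gold_assert_single(pid, eid, fm, cond,
                                            age_onset(age)))
    },
    abort(paste0("unknown phenomenon: ", phenomenon),
          class = "fhh_param_error")
  )
  out$phenomenon <- phenomenon
  out$ambiguous <- FALSE
  out
}

bo_capable <- c("structured_only", "supplement_site", "supplement_onset",
                "relative_correction", "conjunction", "side_only",
                "multiplicity", "uncertainty", "deceased", "gene",
                "exclusion_context")
crc_capable <- c(bo_capable, "syndrome_override")

#' Generate a synthetic FHH corpus with gold annotations
#'
#' Produces patients, FHH entries whose comments instantiate the configured
#' phenomena, constructive gold relations (the generator knows which
#' relative, condition and onset it intended), gold assertions and gold
#' per-cohort eligibility (the criteria engine applied to the gold
#' assertions under `config`). Identical seeds give identical corpora.
#'
#' @param params an [sim_params()]
#' @param config an [fhh_config()] used for gold eligibility
#' @return a list of class `fhh_corpus` with `patients`, `entries`,
#'   `gold_relations`, `gold_assertions`, `gold_eligibility`, `params`
#' @export
generate_corpus <- function(params = sim_params(), config = fhh_config()) {
  lex <- config$lexicon
  with_seed(params$seed, {
    patients <- tibble(
      patient_id = sprintf("P%04d", seq_len(params$n_patients)),
      age = sample(25:60, params$n_patients, replace = TRUE),
      sex = sample(c("FEMALE", "MALE"), params$n_patients, replace = TRUE),
      ashkenazi_jewish = runif(params$n_patients) < params$p_ashkenazi)
    designate_bo <- runif(params$n_patients) < params$p_eligible_bo
    designate_crc <- runif(params$n_patients) < params$p_eligible_crc

    entries <- list(); gold_rel <- list(); gold_assert <- list()
    meta <- list()
    eid_n <- 0L
    for (i in seq_len(params$n_patients)) {
      pid <- patients$patient_id[i]
      n_free <- min(params$max_entries,
                    max(1L, rpois(1, max(params$mean_entries - 1, 0)) + 1L))
      plan <- tibble(qualify = character(0))
      if (designate_bo[i]) plan <- bind_rows(plan, tibble(qualify = "bo"))
      if (designate_crc[i]) plan <- bind_rows(plan, tibble(qualify = "crc"))
      plan <- bind_rows(plan, tibble(qualify = rep("none", n_free)))
      for (j in seq_len(nrow(plan))) {
        qualify <- plan$qualify[j]
        pool <- names(params$phenomena)[params$phenomena > 0]
        if (qualify == "bo") pool <- intersect(pool, bo_capable)
        if (qualify == "crc") pool <- intersect(pool, crc_capable)
        phen <- if (qualify == "none") {
          sample(names(params$phenomena), 1, prob = params$phenomena)
        } else sample1(pool)
        eid_n <- eid_n + 1L
        eid <- sprintf("E%05d", eid_n)
        built <- sim_build_entry(phen, pid, eid, qualify, lex)
        entries[[length(entries) + 1]] <- c(
          list(patient_id = pid, entry_id = eid), built$entry)
        gold_rel[[length(gold_rel) + 1]] <- built$gold_rel
        gold_assert[[length(gold_assert) + 1]] <- built$gold_assert
        meta[[length(meta) + 1]] <- tibble(
          entry_id = eid, phenomenon = built$phenomenon,
          injected = qualify != "none", ambiguous = built$ambiguous)
      }
    }
    ent_tbl <- bind_rows(lapply(entries, as_tibble))
    entries_tbl <- fhh_entry(
      patient_id = ent_tbl$patient_id, entry_id = ent_tbl$entry_id,
      condition_code = ent_tbl$condition_code,
      relative_code = ent_tbl$relative_code,
      onset_age = ent_tbl$onset_age, comment = ent_tbl$comment,
      entry_date = "2019-01-01")
    meta_tbl <- bind_rows(meta)
    entries_tbl <- left_join(entries_tbl, meta_tbl, by = "entry_id")
    class(entries_tbl) <- c("fhh_entries", class(tibble()))

    gold_assertions <- bind_rows(gold_assert)
    gold_relations <- bind_rows(gold_rel)
    profiles <- patient_profiles(entries_tbl, patients)
    gold_eligibility <- bind_rows(lapply(profiles, function(pr) {
      a <- gold_assertions[gold_assertions$patient_id == pr$patient_id, ]
      bind_rows(evaluate_breast_ovarian(pr, a, config),
                evaluate_colorectal(pr, a, config))
    }))
    gold_eligibility$mode <- "GOLD"

    structure(list(params = params, patients = patients,
                   entries = entries_tbl,
                   gold_relations = gold_relations,
                   gold_assertions = gold_assertions,
                   gold_eligibility = gold_eligibility),
              class = "fhh_corpus")
  })
}

#' Apply seeded typos to comment condition terms
#'
#' Emulates data-entry typos ("bladder" -> "bladdler"): at the given rate, a
#' random duplicate letter is inserted inside a condition term found in the
#' comment. Gold annotations are unchanged: a typo is intended to be missed,
#' so recall on a perturbed corpus can only drop.
#'
#' @param corpus an `fhh_corpus`
#' @param rate per-entry perturbation probability in [0, 1]
#' @param seed integer seed
#' @return the perturbed corpus (entries gain a `typo` column)
#' @export
perturb_typos <- function(corpus, rate, seed = 1) {
  if (rate < 0 || rate > 1) {
    abort("rate must be in [0, 1]", class = "fhh_param_error")
  }
  lex <- default_lexicon()
  terms <- lex$conditions$term[nchar(lex$conditions$term) >= 4]
  pat <- paste(vapply(terms, term_pattern, character(1)), collapse = "|")
  entries <- corpus$entries
  entries$typo <- FALSE
  if (rate > 0) {
    with_seed(seed, {
      for (i in seq_len(nrow(entries))) {
        com <- entries$comment[i]
        if (!nzchar(com)) next
        loc <- str_locate_all(str_to_lower(com), pat)[[1]]
        if (nrow(loc) == 0) next
        if (runif(1) >= rate) next
        s <- loc[1, 1]; e <- loc[1, 2]
        pos <- sample(seq(s + 1L, e - 1L), 1)
        entries$comment[i] <- paste0(substr(com, 1, pos),
                                     substr(com, pos, nchar(com)))
        entries$typo[i] <- TRUE
      }
    })
  }
  corpus$entries <- entries
  corpus
}

#' Write a corpus to disk
#'
#' Emits the delimited FHH table, the patient metadata table, the gold
#' relation keys and assertions as CSV, and gold eligibility as JSON lines.
#'
#' @param corpus an `fhh_corpus`
#' @param prefix output path prefix
#' @return character vector of written paths, invisibly
#' @export
write_corpus <- function(corpus, prefix) {
  paths <- c(entries = paste0(prefix, "_entries.csv"),
             patients = paste0(prefix, "_patients.csv"),
             gold_relations = paste0(prefix, "_gold_relations.csv"),
             gold_assertions = paste0(prefix, "_gold_assertions.csv"),
             gold_eligibility = paste0(prefix, "_gold_eligibility.jsonl"))
  write_fhh_table(corpus$entries, paths["entries"])
  write.csv(corpus$patients, paths["patients"], row.names = FALSE)
  write.csv(corpus$gold_relations, paths["gold_relations"],
            row.names = FALSE)
  write.csv(corpus$gold_assertions, paths["gold_assertions"],
            row.names = FALSE)
  write_eligibility(corpus$gold_eligibility, paths["gold_eligibility"])
  invisible(paths)
}
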