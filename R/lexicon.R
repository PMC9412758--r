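#' Default extraction lexicon
#'
#' The lexicon drives every matching step: cancer-site terms and synonyms,
#' cancer syndromes, pathogenic genes, family-member terms with their
#' normalized code, degree of relationship, sex and (when the term itself
#' carries it) side of the family, onset phrase patterns, uncertainty cues,
#' exclusion contexts, condition-override terms and multiplicity number
#' words. All tables are plain tibbles and can be edited, written to CSV with
#' [write_lexicon()] and reloaded with [read_lexicon()]; EHR code lists vary
#' by site, so the shipped enumerations are deliberately user-editable.
#'
#' @return a list of class `fhh_lexicon`
#' @export
default_lexicon <- function() {
  site <- function(norm, terms) tibble(
    term = terms, label = norm, norm = norm, class = "CANCER", site = TRUE
  )
  conditions <- bind_rows(
    site("BLADDER", c("bladder")),
    site("BREAST", c("breast")),
    site("BRAIN", c("brain")),
    site("COLON", c("colon", "colorectal")),
    site("KIDNEY", c("kidney", "renal")),
    site("OVARIAN", c("ovarian", "ovary")),
    site("PANCREAS", c("pancreatic", "pancreas")),
    site("PROSTATE", c("prostate")),
    site("RECTAL", c("rectal", "rectum")),
    site("STOMACH", c("stomach", "gastric")),
    site("SMALL_INTESTINE", c("small intestine", "small bowel", "ileum")),
    site("URETERAL", c("ureteral", "ureter")),
    site("URETHRAL", c("urethral", "urethra")),
    # reconstruction: endometrial/uterine is needed by the colorectal
    # criteria even though it is not in the core site-subtype list
    site("ENDOMETRIAL", c("endometrial", "uterine", "uterus", "endometrium")),
    tibble(term = c("cancer", "ca", "carcinoma"),
           label = "CANCER", norm = "CANCER", class = "CANCER", site = FALSE),
    tibble(
      term = c("lynch syndrome", "lynch", "hnpcc",
               "cowden syndrome", "cowden",
               "li-fraumeni syndrome", "li-fraumeni",
               "familial adenomatous polyposis", "fap",
               "serrated polyposis", "polyposis", "apc"),
      norm = c("LYNCH", "LYNCH", "HNPCC", "COWDEN", "COWDEN",
               "LI_FRAUMENI", "LI_FRAUMENI", "FAP", "FAP",
               "SERRATED_POLYPOSIS", "POLYPOSIS", "APC"),
      label = "SYNDROME", class = "SYNDROME", site = FALSE),
    tibble(
      term = c("brca1/2", "brca1", "brca2", "brca", "chek2", "atm", "palb2",
               "tp53", "pten", "cdh1", "mlh1", "msh2", "pms2", "msh6",
               "epcam", "myh", "mutyh"),
      norm = c("BRCA1/2", "BRCA1", "BRCA2", "BRCA1/2", "CHEK2", "ATM",
               "PALB2", "TP53", "PTEN", "CDH1", "MLH1", "MSH2", "PMS2",
               "MSH6", "EPCAM", "MYH", "MUTYH"),
      label = "GENE_MUT", class = "GENE_MUT", site = FALSE)
  )

  rel <- function(terms, code, degree, sex, side = "UNKNOWN",
                  specific = TRUE) tibble(
    term = terms, code = code, degree = degree, sex = sex, side = side,
    specific = specific
  )
  relatives <- bind_rows(
    rel(c("mother", "mom"), "MOTHER", 1L, "FEMALE", "MATERNAL"),
    rel(c("father", "dad"), "FATHER", 1L, "MALE", "PATERNAL"),
    rel(c("sister", "sis"), "SISTER", 1L, "FEMALE", "BOTH"),
    rel(c("brother"), "BROTHER", 1L, "MALE", "BOTH"),
    rel(c("sibling"), "SIBLING", 1L, "UNKNOWN", "BOTH"),
    rel(c("daughter"), "DAUGHTER", 1L, "FEMALE", "BOTH"),
    rel(c("son"), "SON", 1L, "MALE", "BOTH"),
    rel(c("child"), "CHILD", 1L, "UNKNOWN", "BOTH"),
    rel(c("half-sister"), "HALF_SISTER", 2L, "FEMALE"),
    rel(c("half-brother"), "HALF_BROTHER", 2L, "MALE"),
    rel(c("grandmother", "grandma"), "GRANDMOTHER", 2L, "FEMALE"),
    rel(c("grandfather", "grandpa"), "GRANDFATHER", 2L, "MALE"),
    rel(c("maternal grandmother"), "MATERNAL_GRANDMOTHER", 2L, "FEMALE",
        "MATERNAL"),
    rel(c("paternal grandmother"), "PATERNAL_GRANDMOTHER", 2L, "FEMALE",
        "PATERNAL"),
    rel(c("maternal grandfather"), "MATERNAL_GRANDFATHER", 2L, "MALE",
        "MATERNAL"),
    rel(c("paternal grandfather"), "PATERNAL_GRANDFATHER", 2L, "MALE",
        "PATERNAL"),
    rel(c("aunt", "auntie"), "AUNT", 2L, "FEMALE"),
    rel(c("uncle"), "UNCLE", 2L, "MALE"),
    rel(c("maternal aunt"), "MATERNAL_AUNT", 2L, "FEMALE", "MATERNAL"),
    rel(c("paternal aunt"), "PATERNAL_AUNT", 2L, "FEMALE", "PATERNAL"),
    rel(c("maternal uncle"), "MATERNAL_UNCLE", 2L, "MALE", "MATERNAL"),
    rel(c("paternal uncle"), "PATERNAL_UNCLE", 2L, "MALE", "PATERNAL"),
    rel(c("niece"), "NIECE", 2L, "FEMALE"),
    rel(c("nephew"), "NEPHEW", 2L, "MALE"),
    rel(c("granddaughter"), "GRANDDAUGHTER", 2L, "FEMALE", "BOTH"),
    rel(c("grandson"), "GRANDSON", 2L, "MALE", "BOTH"),
    rel(c("great-aunt", "great aunt", "greataunt"), "GREAT_AUNT", 3L,
        "FEMALE"),
    rel(c("great-uncle", "great uncle", "greatuncle"), "GREAT_UNCLE", 3L,
        "MALE"),
    rel(c("great-grandmother", "great grandmother"), "GREAT_GRANDMOTHER",
        3L, "FEMALE"),
    rel(c("great-grandfather", "great grandfather"), "GREAT_GRANDFATHER",
        3L, "MALE"),
    rel(c("cousin"), "COUSIN", 3L, "UNKNOWN"),
    # nonspecific side-only phrases: not a person, only a side feature
    rel(c("father's side", "father side", "paternal side", "dad's side"),
        "SIDE_ONLY", NA_integer_, "UNKNOWN", "PATERNAL", specific = FALSE),
    rel(c("mother's side", "mother side", "maternal side", "mom's side"),
        "SIDE_ONLY", NA_integer_, "UNKNOWN", "MATERNAL", specific = FALSE)
  )

  # structured condition codes as stored in the coded condition field
  cc <- function(code, label, norm, class = "CANCER", relevant = TRUE) tibble(
    code = code, label = label, norm = norm, class = class,
    relevant = relevant
  )
  condition_codes <- bind_rows(
    cc("CANCER", "CANCER", "CANCER"),
    cc("CANCER, OTHER", "CANCER", "CANCER"),
    cc("CANCER, BLADDER", "BLADDER", "BLADDER"),
    cc("CANCER, BREAST", "BREAST", "BREAST"),
    cc("CANCER, BRAIN", "BRAIN", "BRAIN"),
    cc("CANCER, COLON", "COLON", "COLON"),
    cc("CANCER, KIDNEY", "KIDNEY", "KIDNEY"),
    cc("CANCER, OVARIAN", "OVARIAN", "OVARIAN"),
    cc("CANCER, PANCREAS", "PANCREAS", "PANCREAS"),
    cc("CANCER, PROSTATE", "PROSTATE", "PROSTATE"),
    cc("CANCER, RECTAL", "RECTAL", "RECTAL"),
    cc("CANCER, STOMACH", "STOMACH", "STOMACH"),
    cc("CANCER, SMALL INTESTINE", "SMALL_INTESTINE", "SMALL_INTESTINE"),
    cc("CANCER, URETERAL", "URETERAL", "URETERAL"),
    cc("CANCER, URETHRAL", "URETHRAL", "URETHRAL"),
    cc("CANCER, ENDOMETRIAL", "ENDOMETRIAL", "ENDOMETRIAL"),
    cc("CANCER, UTERINE", "ENDOMETRIAL", "ENDOMETRIAL"),
    cc("LYNCH SYNDROME", "SYNDROME", "LYNCH", class = "SYNDROME"),
    cc("HNPCC", "SYNDROME", "HNPCC", class = "SYNDROME"),
    cc("FAP", "SYNDROME", "FAP", class = "SYNDROME"),
    cc("COWDEN SYNDROME", "SYNDROME", "COWDEN", class = "SYNDROME"),
    cc("LI-FRAUMENI SYNDROME", "SYNDROME", "LI_FRAUMENI",
       class = "SYNDROME"),
    cc("BRCA1", "GENE_MUT", "BRCA1", class = "GENE_MUT"),
    cc("BRCA2", "GENE_MUT", "BRCA2", class = "GENE_MUT"),
    cc("MLH1", "GENE_MUT", "MLH1", class = "GENE_MUT"),
    cc("MSH2", "GENE_MUT", "MSH2", class = "GENE_MUT"),
    cc("DIABETES", "OTHER", "DIABETES", class = "OTHER", relevant = FALSE),
    cc("HYPERTENSION", "OTHER", "HYPERTENSION", class = "OTHER",
       relevant = FALSE),
    cc("HEART DISEASE", "OTHER", "HEART_DISEASE", class = "OTHER",
       relevant = FALSE),
    cc("STROKE", "OTHER", "STROKE", class = "OTHER", relevant = FALSE),
    cc("ASTHMA", "OTHER", "ASTHMA", class = "OTHER", relevant = FALSE),
    cc("DEPRESSION", "OTHER", "DEPRESSION", class = "OTHER",
       relevant = FALSE),
    cc("ARTHRITIS", "OTHER", "ARTHRITIS", class = "OTHER", relevant = FALSE),
    cc("OTHER", "OTHER", "OTHER", class = "OTHER", relevant = FALSE)
  )

  relative_codes <- relatives |>
    filter(.data$specific) |>
    distinct(.data$code, .keep_all = TRUE) |>
    transmute(code = .data$code, degree = .data$degree, sex = .data$sex,
              side = .data$side)

  structure(list(
    conditions = conditions,
    relatives = relatives,
    condition_codes = condition_codes,
    relative_codes = relative_codes,
    uncertainty_cues = c("\\bpossible\\b", "\\bpossibly\\b",
                         "\\bprobable\\b", "\\bprobably\\b", "\\bmaybe\\b",
                         "\\?", "\\bunsure\\b", "\\bunknown type\\b",
                         "\\bsuspected\\b"),
    fm_exclusion = c("(?:lives?|lived|living)\\s+with(?:\\s+(?:his|her|their))?[\\s,]*$",
                     "takes?\\s+care\\s+of[\\s,]*$",
                     "caregiver\\s+(?:for|of)[\\s,]*$"),
    onset_exclusion = c("when\\s+(?:pt|patient)\\s+was[\\s,]*$"),
    condition_overrides = c("precancer", "pre-cancer", "benign", "cyst",
                            "no cancer", "not cancer"),
    conjunctions = "(?:\\band\\b|\\balso\\b|&|\\+)[\\s,]*$",
    number_words = c(one = 1L, two = 2L, three = 3L, four = 4L, five = 5L,
                     six = 6L, seven = 7L, eight = 8L, nine = 9L, ten = 10L),
    crc_syndromes = c("LYNCH", "HNPCC", "FAP", "APC", "POLYPOSIS",
                      "SERRATED_POLYPOSIS")
  ), class = "fhh_lexicon")
}

# Regex for one lexicon term: case-insensitive, hyphen/space interchangeable,
# optional plural "s" for relative terms, word-bounded.
term_pattern <- function(term, plural = FALSE) {
  esc <- gsub("([.\\\\+*?^$(){}=!<>|:#\\[\\]-])", "\\\\\\1", term,
              perl = TRUE)
  esc <- gsub("\\\\-|\\s+", "[ -]", esc)
  paste0("\\b", esc, if (plural) "s?", "\\b")
}

# cheap fixed-string prefilter stem: the leading alphanumeric run of a term
term_stem <- function(term) {
  sub("[^a-z0-9].*$", "", str_to_lower(term))
}

lookup_condition_code <- function(code, lexicon) {
  key <- normalize_code(code)
  if (is.na(key)) return(NULL)
  hit <- lexicon$condition_codes[lexicon$condition_codes$code == key, ]
  if (nrow(hit) == 0) NULL else hit[1, ]
}

lookup_relative_code <- function(code, lexicon) {
  key <- normalize_code(code)
  if (is.na(key)) return(NULL)
  key <- gsub(" ", "_", key)
  hit <- lexicon$relative_codes[lexicon$relative_codes$code == key, ]
  if (nrow(hit) == 0) NULL else hit[1, ]
}

#' Write a lexicon to a directory of CSV files
#'
#' @param lexicon an `fhh_lexicon`
#' @param dir output directory (created if missing)
#' @return `dir`, invisibly
#' @export
write_lexicon <- function(lexicon, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tabs <- c("conditions", "relatives", "condition_codes", "relative_codes")
  for (t in tabs) {
    write.csv(lexicon[[t]], file.path(dir, paste0(t, ".csv")),
              row.names = FALSE)
  }
  scalars <- lexicon[setdiff(names(lexicon), tabs)]
  scalars$number_words <- as.list(scalars$number_words)
  jsonlite::write_json(scalars, file.path(dir, "rules.json"),
                       auto_unbox = FALSE, pretty = TRUE)
  invisible(dir)
}

#' Read a lexicon from a directory written by [write_lexicon()]
#'
#' @param dir directory containing the lexicon CSV/JSON files
#' @return an `fhh_lexicon`
#' @export
read_lexicon <- function(dir) {
  tabs <- c("conditions", "relatives", "condition_codes", "relative_codes")
  out <- list()
  for (t in tabs) {
    path <- file.path(dir, paste0(t, ".csv"))
    if (!file.exists(path)) {
      abort(paste0("lexicon file missing: ", path), class = "fhh_config_error")
    }
    out[[t]] <- as_tibble(read.csv(path, stringsAsFactors = FALSE))
  }
  rules <- jsonlite::read_json(file.path(dir, "rules.json"),
                               simplifyVector = TRUE)
  out <- c(out, rules)
  out$number_words <- vapply(out$number_words, as.integer, integer(1))
  structure(out, class = "fhh_lexicon")
}
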