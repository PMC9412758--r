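# Independent brute-force oracles; deliberately naive reimplementations
# kept separate from the package's code paths.

# Expected family member/condition pairing: plain double loop over the
# reconciled entity table, applying the documented scope definition.
oracle_condition_pairs <- function(entities) {
  act <- entities[entities$status == "ACTIVE", ]
  fms <- act[act$class == "FAMILYMEMBER", ]
  conds <- act[act$class %in% c("CANCER", "SYNDROME", "GENE_MUT"), ]
  pairs <- 0L
  if (nrow(conds) == 0) return(0L)
  for (ci in seq_len(nrow(conds))) {
    in_scope <- 0L
    for (fi in seq_len(nrow(fms))) {
      if (fms$is_structural[fi] ||
          fms$seg_id[fi] == conds$seg_id[ci]) {
        in_scope <- in_scope + 1L
      }
    }
    if (in_scope == 0L) in_scope <- nrow(fms)
    pairs <- pairs + in_scope
  }
  pairs
}

# Exhaustive criteria oracle: every criterion checked by explicit iteration
# over assertion rows (no vectorized reuse of the engine's helpers).
oracle_criteria <- function(cohort, assertions, ashkenazi = NA,
                            config = fhh_config()) {
  a <- assertions
  if (config$uncertainty_policy == "EXCLUDE" && nrow(a) > 0) {
    a <- a[!a$uncertain, ]
  }
  deg_tab <- list(MOTHER = 1, FATHER = 1, SISTER = 1, BROTHER = 1,
                  SIBLING = 1, DAUGHTER = 1, SON = 1, CHILD = 1,
                  GRANDMOTHER = 2, GRANDFATHER = 2,
                  MATERNAL_GRANDMOTHER = 2, PATERNAL_GRANDMOTHER = 2,
                  MATERNAL_GRANDFATHER = 2, PATERNAL_GRANDFATHER = 2,
                  AUNT = 2, UNCLE = 2, MATERNAL_AUNT = 2, PATERNAL_AUNT = 2,
                  MATERNAL_UNCLE = 2, PATERNAL_UNCLE = 2, NIECE = 2,
                  NEPHEW = 2, HALF_SISTER = 2, HALF_BROTHER = 2,
                  GRANDDAUGHTER = 2, GRANDSON = 2,
                  GREAT_AUNT = 3, GREAT_UNCLE = 3, GREAT_GRANDMOTHER = 3,
                  GREAT_GRANDFATHER = 3, COUSIN = 3)
  side_tab <- list(MOTHER = "MATERNAL", FATHER = "PATERNAL",
                   SISTER = "BOTH", BROTHER = "BOTH", SIBLING = "BOTH",
                   DAUGHTER = "BOTH", SON = "BOTH", CHILD = "BOTH",
                   MATERNAL_GRANDMOTHER = "MATERNAL",
                   MATERNAL_GRANDFATHER = "MATERNAL",
                   PATERNAL_GRANDMOTHER = "PATERNAL",
                   PATERNAL_GRANDFATHER = "PATERNAL",
                   MATERNAL_AUNT = "MATERNAL", PATERNAL_AUNT = "PATERNAL",
                   MATERNAL_UNCLE = "MATERNAL", PATERNAL_UNCLE = "PATERNAL",
                   GRANDDAUGHTER = "BOTH", GRANDSON = "BOTH")
  deg <- function(row) {
    d <- deg_tab[[row$relative_code]]
    if (is.null(d)) NA_integer_ else d
  }
  side <- function(row) {
    if (!is.na(row$side) && row$side != "UNKNOWN") return(row$side)
    s <- side_tab[[row$relative_code]]
    if (is.null(s)) "UNKNOWN" else s
  }
  onset_le <- function(row, t) {
    if (is.na(row$onset_kind)) return(FALSE)
    if (row$onset_kind == "AGE") return(row$onset_lower <= t)
    if (row$onset_kind == "RANGE") {
      if (row$onset_inferred && !config$inferred_range_participates) {
        return(FALSE)
      }
      if (config$range_threshold_policy == "OPTIMISTIC") {
        return(row$onset_lower <= t)
      }
      return(row$onset_upper <= t)
    }
    FALSE
  }
  colon <- if (config$colon_definition == "COLON_RECTAL") {
    c("COLON", "RECTAL")
  } else "COLON"
  side_tally <- function(rows_keep) {
    m <- 0L; p <- 0L
    for (i in rows_keep) {
      s <- side(a[i, ])
      n <- a$count[i]
      if (s == "MATERNAL") m <- m + n
      if (s == "PATERNAL") p <- p + n
      if (s == "BOTH") { m <- m + n; p <- p + n }
      if (s == "UNKNOWN" && config$unknown_side_counts) {
        m <- m + n; p <- p + n
      }
    }
    max(m, p)
  }
  matched <- character(0)
  n <- nrow(a)
  if (cohort == "BREAST_OVARIAN") {
    for (i in seq_len(n)) {
      r <- a[i, ]; d <- deg(r)
      if (r$condition == "BREAST" && !is.na(d) && d <= 2 &&
          onset_le(r, 45)) matched <- union(matched, "BO1")
      if (r$condition == "OVARIAN" && !is.na(d) && d <= 2) {
        matched <- union(matched, "BO2")
      }
      if (r$condition == "PANCREAS" && !is.na(d) && d == 1) {
        matched <- union(matched, "BO3")
      }
      if (r$condition == "BREAST" && r$sex == "MALE") {
        matched <- union(matched, "BO4")
      }
      if (isTRUE(ashkenazi) && r$condition %in% c("BREAST", "PROSTATE")) {
        matched <- union(matched, "BO6")
      }
      if ((r$condition_class == "GENE_MUT" &&
             r$condition %in% c("BRCA1", "BRCA2", "BRCA1/2", "CHEK2",
                                "ATM", "PALB2", "TP53", "PTEN", "CDH1")) ||
          (r$condition_class == "SYNDROME" &&
             r$condition %in% c("COWDEN", "LI_FRAUMENI"))) {
        matched <- union(matched, "BO7")
      }
    }
    bo5_rows <- integer(0)
    for (i in seq_len(n)) {
      r <- a[i, ]; d <- deg(r)
      if (r$condition %in% c("BREAST", "PROSTATE") && !is.na(d) && d <= 2) {
        bo5_rows <- c(bo5_rows, i)
      }
    }
    if (side_tally(bo5_rows) >= 3) matched <- union(matched, "BO5")
  } else {
    for (i in seq_len(n)) {
      r <- a[i, ]; d <- deg(r)
      c1_syn <- r$condition_class == "SYNDROME" &&
        r$condition %in% c("LYNCH", "HNPCC", "FAP", "APC",
                           "SERRATED_POLYPOSIS", "POLYPOSIS") &&
        (config$comment_polyposis || r$condition_source == "structured")
      if ((r$condition_class == "GENE_MUT" &&
             r$condition %in% c("MLH1", "MSH2", "PMS2", "MSH6", "EPCAM",
                                "MYH", "MUTYH")) || c1_syn) {
        matched <- union(matched, "C1")
      }
      if (r$condition %in% colon && !is.na(d) && d == 1 &&
          onset_le(r, 50)) matched <- union(matched, "C2")
      if (r$condition == "ENDOMETRIAL" && !is.na(d) && d == 1 &&
          onset_le(r, 50)) matched <- union(matched, "C3")
    }
    c4_rows <- integer(0)
    c4_set <- c(colon, "ENDOMETRIAL", "OVARIAN", "STOMACH",
                "SMALL_INTESTINE", "KIDNEY", "URETERAL", "BLADDER",
                "URETHRAL", "BRAIN", "PANCREAS")
    for (i in seq_len(n)) {
      r <- a[i, ]; d <- deg(r)
      ok <- (r$condition_class == "CANCER" && r$condition %in% c4_set) ||
        (r$condition_class == "SYNDROME" &&
           r$condition %in% c("LYNCH", "HNPCC"))
      if (ok && !is.na(d) && d <= 2) c4_rows <- c(c4_rows, i)
    }
    if (side_tally(c4_rows) >= 3) matched <- union(matched, "C4")
  }
  sort(matched)
}

# random assertion tables for the criteria-equivalence property
random_assertions <- function(n, seed) {
  set.seed(seed)
  rels <- c("MOTHER", "FATHER", "SISTER", "BROTHER", "AUNT", "UNCLE",
            "GRANDMOTHER", "MATERNAL_GRANDMOTHER", "PATERNAL_UNCLE",
            "GREAT_AUNT", "COUSIN", "SON", "NIECE")
    conds <- list(
    list("BREAST", "CANCER"), list("OVARIAN", "CANCER"),
    list("COLON", "CANCER"), list("RECTAL", "CANCER"),
    list("PANCREAS", "CANCER"), list("PROSTATE", "CANCER"),
    list("STOMACH", "CANCER"), list("ENDOMETRIAL", "CANCER"),
    list("KIDNEY", "CANCER"), list("CANCER", "CANCER"),
    list("LYNCH", "SYNDROME"), list("COWDEN", "SYNDROME"),
    list("FAP", "SYNDROME"),
    list("BRCA1", "GENE_MUT"), list("MLH1", "GENE_MUT"),
    list("ATM", "GENE_MUT"))
  rows <- lapply(seq_len(n), function(i) {
    cd <- conds[[sample.int(length(conds), 1)]]
    kind <- sample(c(NA, "AGE", "RANGE", "PERIOD", "STRING"), 1)
    lower <- if (is.na(kind)) NA_real_ else sample(20:80, 1)
    upper <- if (!is.na(kind) && kind == "RANGE") lower + 9 else lower
    sex_pool <- if (cd[[1]] %in% c("BREAST", "PROSTATE")) {
      c("FEMALE", "MALE")
    } else c("FEMALE", "MALE", "UNKNOWN")
    make_assertion(
      relative_code = sample(rels, 1), condition = cd[[1]],
      condition_class = cd[[2]],
      side = sample(c("UNKNOWN", "MATERNAL", "PATERNAL", "BOTH"), 1,
                    prob = c(.4, .25, .25, .1)),
      sex = sample(sex_pool, 1),
      onset_kind = kind, onset_lower = lower, onset_upper = upper,
      uncertain = runif(1) < 0.2,
      count = sample(1:2, 1),
      onset_inferred = !is.na(kind) && kind == "RANGE" && runif(1) < 0.2,
      condition_source = sample(c("structured", "comment"), 1))
  })
  dplyr::bind_rows(rows)
}
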