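entities_proto <- tibble(
  ent_id = character(), entry_id = character(),
  start = integer(), end = integer(), surface = character(),
  label = character(), class = character(), norm = character(),
  is_structural = logical(), uncertainty = logical(), status = character(),
  code = character(), side = character(), sex = character(),
  degree = integer(), multiplicity = integer(), instance = integer(),
  onset_kind = character(), onset_lower = double(), onset_upper = double(),
  inferred = logical(), expanded = logical(), seg_id = integer(),
  ignore_reason = character()
)

new_entities <- function(...) {
  proto <- entities_proto
  rows <- bind_rows(...)
  if (nrow(rows) == 0) return(proto)
  for (col in names(proto)) {
    if (!col %in% names(rows)) {
      rows[[col]] <- vctrs_default(proto[[col]], nrow(rows))
    }
  }
  rows <- rows[, names(proto)]
  rows$uncertainty[is.na(rows$uncertainty)] <- FALSE
  rows$is_structural[is.na(rows$is_structural)] <- FALSE
  rows$status[is.na(rows$status)] <- "ACTIVE"
  rows$side[is.na(rows$side)] <- "UNKNOWN"
  rows$sex[is.na(rows$sex)] <- "UNKNOWN"
  rows$multiplicity[is.na(rows$multiplicity)] <- 1L
  rows$instance[is.na(rows$instance)] <- 1L
  rows$inferred[is.na(rows$inferred)] <- FALSE
  rows$expanded[is.na(rows$expanded)] <- FALSE
  rows
}

vctrs_default <- function(proto_col, n) {
  rep(if (is.character(proto_col)) NA_character_
      else if (is.integer(proto_col)) NA_integer_
      else if (is.double(proto_col)) NA_real_
      else NA, n)
}

#' Validate an entity table
#'
#' Checks the structural invariants every pipeline stage must maintain:
#' spans inside the text, multiplicity and instance at least 1, and no two
#' ACTIVE same-label entities overlapping.
#'
#' @param entities an entity tibble
#' @param marked the `fhh_marked` the spans index into (optional)
#' @return `entities`, invisibly; aborts on violation
#' @export
validate_entities <- function(entities, marked = NULL) {
  if (nrow(entities) == 0) return(invisible(entities))
  stopifnot(all(entities$start >= 0), all(entities$end > entities$start))
  if (!is.null(marked)) stopifnot(all(entities$end <= nchar(marked$text)))
  stopifnot(all(entities$multiplicity >= 1), all(entities$instance >= 1))
  act <- entities[entities$status == "ACTIVE", ]
  if (nrow(act) > 1) {
    for (lab in unique(act$label)) {
      e <- act[act$label == lab & act$instance == 1L, ]
      if (nrow(e) > 1) {
        e <- e[order(e$start), ]
        if (any(e$start[-1] < e$end[-nrow(e)])) {
          abort(paste0("overlapping ACTIVE entities of label ", lab),
                class = "fhh_invariant_error")
        }
      }
    }
  }
  invisible(entities)
}

# ---- onset parsing ---------------------------------------------------------

onset_comment_patterns <- function() {
  list(
    # deceased age: "deceased at age 60 years", "died at 60"
    list(label = "DECEASED_AGE", priority = 1,
         pattern = "(?:deceased|died|passed(?:\\s+away)?)\\s+(?:at\\s+)?(?:the\\s+)?(?:age\\s+)?(?:of\\s+)?\\d{1,3}(?:\\s+years?(?:\\s+old)?)?"),
    # decade range: "in his 30s", "the late 50s", "early 40's", "30s"
    list(label = "ONSET_RANGE", priority = 2,
         pattern = "(?:in\\s+(?:his|her|their)\\s+)?(?:the\\s+)?(?:(?:early|late)\\s+)?\\d0'?s\\b"),
    # calendar period: "in 1985"
    list(label = "ONSET_PERIOD", priority = 3,
         pattern = "in\\s+(?:19|20)\\d{2}\\b"),
    # exact age: "dx at age of 52", "age 52", "at 45", "@ 45", "aged 45"
    list(label = "ONSET_AGE", priority = 4,
         pattern = "(?:(?:dx|dxd|diagnosed|dx'd)\\s+)?(?:at\\s+)?age(?:d)?(?:\\s+of)?\\s+\\d{1,3}\\b|(?:at|@)\\s+\\d{1,3}\\b"),
    # non-numeric onset descriptions
    list(label = "ONSET_STRING", priority = 5,
         pattern = "\\d+\\s+years?\\s+ago\\b|postmenopaus\\w*|postmenstruation|premenopaus\\w*|as\\s+a\\s+child\\b|in\\s+childhood\\b|at\\s+a\\s+young\\s+age\\b")
  )
}

#' Parse an onset mention
#'
#' Classifies the surface text of an onset mention into one of the four
#' onset subtypes and computes its bounds in years:
#' exact ages give `AGE` with equal bounds; decade phrases give `RANGE`
#' (`"late 50s"` -> 55--59, `"early 30s"` -> 30--34, bare `"40s"` -> 40--49);
#' 4-digit calendar years give `PERIOD` (no bounds, since no birth year is
#' available); anything else is `STRING`.
#'
#' @param span_text the onset mention text
#' @return a list with `kind`, `lower`, `upper`, `raw`
#' @export
parse_onset <- function(span_text) {
  txt <- str_to_lower(span_text)
  dec <- str_match(txt, "(early|late)?\\s*(\\d)0'?s\\b")
  if (!is.na(dec[1, 1])) {
    base <- as.numeric(dec[1, 3]) * 10
    qual <- dec[1, 2]
    bounds <- if (!is.na(qual) && qual == "early") c(base, base + 4)
      else if (!is.na(qual) && qual == "late") c(base + 5, base + 9)
      else c(base, base + 9)
    return(list(kind = "RANGE", lower = bounds[1], upper = bounds[2],
                raw = span_text))
  }
  if (str_detect(txt, "\\b(?:19|20)\\d{2}\\b")) {
    return(list(kind = "PERIOD", lower = NA_real_, upper = NA_real_,
                raw = span_text))
  }
  num <- str_match(txt, "(\\d{1,3})")[, 2]
  if (!is.na(num) && as.numeric(num) <= 120) {
    age <- as.numeric(num)
    return(list(kind = "AGE", lower = age, upper = age, raw = span_text))
  }
  list(kind = "STRING", lower = NA_real_, upper = NA_real_, raw = span_text)
}

#' Parse a family-member multiplicity prefix
#'
#' `"2× sisters"`, `"2 x sisters"`, `"x2 sisters"` and number words up
#' to ten (`"three aunts"`) yield the corresponding count; anything else
#' yields 1. A literal count of 0 is treated as 1 with a warning.
#'
#' @param fm_text family-member mention text, including any count prefix
#' @return positive integer count
#' @export
parse_multiplicity <- function(fm_text) {
  txt <- str_to_lower(str_trim(fm_text))
  m <- str_match(txt, "^(\\d+)\\s*[x×]")[, 2]
  if (is.na(m)) m <- str_match(txt, "^[x×]\\s*(\\d+)")[, 2]
  if (is.na(m)) m <- str_match(txt, "^(\\d+)\\s")[, 2]
  if (!is.na(m)) {
    n <- as.integer(m)
    if (n == 0L) {
      warn("multiplicity 0 treated as 1")
      return(1L)
    }
    return(n)
  }
  w <- str_match(txt, paste0("^(", paste(names(number_words_table),
                                         collapse = "|"), ")\\b"))[, 2]
  if (!is.na(w)) return(unname(number_words_table[[w]]))
  1L
}

number_words_table <- c(one = 1L, two = 2L, three = 3L, four = 4L,
                        five = 5L, six = 6L, seven = 7L, eight = 8L,
                        nine = 9L, ten = 10L)

# ---- matching --------------------------------------------------------------

# locate all matches of `pattern` in `text` limited to [lo, hi) (0-based),
# returning 0-based half-open spans
locate_within <- function(text, pattern, lo, hi) {
  seg <- substr(text, lo + 1L, hi)
  locs <- str_locate_all(seg, regex(pattern, ignore_case = TRUE))[[1]]
  fast_tibble(start = as.integer(locs[, 1] - 1L + lo),
              end = as.integer(locs[, 2] + lo))
}

# greedy longest-match, leftmost tie-break, within one label family
resolve_overlaps <- function(cand) {
  if (nrow(cand) == 0) return(cand)
  cand <- cand[order(-(cand$end - cand$start), cand$start,
                     cand$priority %||% 0), ]
  taken <- logical(nrow(cand))
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    ov <- keep & (cand$start < cand$end[i]) & (cand$end > cand$start[i])
    if (!any(ov)) keep[i] <- TRUE
  }
  cand[keep, ][order(cand$start[keep]), ]
}

mult_prefix_pattern <- paste0(
  "(?:(\\d+)\\s*[x×]\\s*|[x×]\\s*(\\d+)\\s*|",
  "\\b(one|two|three|four|five|six|seven|eight|nine|ten)\\s+)$")

#' Match the lexicon against marked text
#'
#' Step-1 lexicon matching: structured-field values are looked up in the
#' coded condition/relative tables (a structured numeric onset becomes a
#' structural `ONSET_AGE`), and the comment region is scanned with the term
#' lexicons (longest match wins, case-insensitive, hyphen/space tolerant).
#' A multiplicity prefix immediately before a relative term is absorbed into
#' the family-member span. Context rules and classification are applied
#' afterwards by [apply_context_rules()] and [classify_entities()].
#'
#' @param marked an `fhh_marked`
#' @param config an [fhh_config()]
#' @return an entity tibble (pre-context)
#' @export
match_lexicon <- function(marked, config = fhh_config()) {
  lex <- config$lexicon
  if (is.null(lex) || nrow(lex$conditions) == 0) {
    abort("empty or missing lexicon", class = "fhh_config_error")
  }
  text <- marked$text
  spans <- marked$spans
  rows <- list()

  # --- structured condition ---
  cond <- spans[spans$field == "condition_code", ]
  hit <- lookup_condition_code(cond$value, lex)
  if (!is.null(hit) && hit$class != "OTHER") {
    rows[[length(rows) + 1]] <- fast_tibble(
      start = cond$value_start, end = cond$value_end, surface = cond$value,
      label = hit$label, class = hit$class, norm = hit$norm,
      is_structural = TRUE)
  }

  # --- structured relative ---
  rel <- spans[spans$field == "relative_code", ]
  rhit <- lookup_relative_code(rel$value, lex)
  if (!is.null(rhit)) {
    rows[[length(rows) + 1]] <- fast_tibble(
      start = rel$value_start, end = rel$value_end, surface = rel$value,
      label = "FAMILYMEMBER", class = "FAMILYMEMBER", norm = rhit$code,
      code = rhit$code, degree = rhit$degree, sex = rhit$sex,
      side = rhit$side, is_structural = TRUE)
  }

  # --- structured onset ---
  ons <- spans[spans$field == "onset_age", ]
  if (!is_blank(ons$value)) {
    age <- suppressWarnings(as.numeric(ons$value))
    if (!is.na(age)) {
      rows[[length(rows) + 1]] <- fast_tibble(
        start = ons$value_start, end = ons$value_end, surface = ons$value,
        label = "ONSET_AGE", class = "ONSET", norm = as.character(age),
        onset_kind = "AGE", onset_lower = age, onset_upper = age,
        is_structural = TRUE)
    }
  }

  # --- comment region ---
  com <- spans[spans$field == "comment", ]
  if (nzchar(com$value)) {
    lo <- com$start
    hi <- com$end
    com_lower <- str_to_lower(com$value)

    # conditions: site terms also match with an optional cancer/ca suffix
    ct <- lex$conditions
    cond_pats <- vapply(ct$term, term_pattern, character(1),
                        USE.NAMES = FALSE)
    cond_pats <- ifelse(ct$site,
                        paste0(cond_pats, "(?:\\s+(?:cancer|ca)\\b)?"),
                        cond_pats)
    present <- vapply(term_stem(ct$term), grepl, logical(1),
                      x = com_lower, fixed = TRUE, USE.NAMES = FALSE)
    cond_cand <- map_dfr(which(present), function(i) {
      loc <- locate_within(text, cond_pats[i], lo, hi)
      if (nrow(loc) == 0) return(NULL)
      loc$label <- ct$label[i]; loc$class <- ct$class[i]
      loc$norm <- ct$norm[i]
      loc$priority <- if (isTRUE(ct$site[i]) || ct$class[i] != "CANCER") 0
                      else 1
      loc
    })
    cond_cand <- resolve_overlaps(cond_cand)
    if (nrow(cond_cand) > 0) {
      cond_cand$surface <- substr(rep(text, nrow(cond_cand)),
                                  cond_cand$start + 1L, cond_cand$end)
      rows[[length(rows) + 1]] <- cond_cand[, c("start", "end", "surface",
                                                "label", "class", "norm")]
    }

    # relatives (with multiplicity prefixes)
    rt <- lex$relatives
    rel_pats <- vapply(rt$term, term_pattern, character(1), plural = TRUE,
                       USE.NAMES = FALSE)
    rpresent <- vapply(term_stem(rt$term), grepl, logical(1),
                       x = com_lower, fixed = TRUE, USE.NAMES = FALSE)
    rel_cand <- map_dfr(which(rpresent), function(i) {
      loc <- locate_within(text, rel_pats[i], lo, hi)
      if (nrow(loc) == 0) return(NULL)
      loc$code <- rt$code[i]; loc$degree <- rt$degree[i]
      loc$sex <- rt$sex[i]
      loc$side <- rt$side[i]
      loc$specific <- rt$specific[i]
      loc$priority <- 0
      loc
    })
    rel_cand <- resolve_overlaps(rel_cand)
    if (nrow(rel_cand) > 0) {
      rel_cand$multiplicity <- 1L
      for (i in seq_len(nrow(rel_cand))) {
        ctx_lo <- max(lo, rel_cand$start[i] - 12L)
        before <- substr(text, ctx_lo + 1L, rel_cand$start[i])
        pm <- str_match(str_to_lower(before), mult_prefix_pattern)
        if (!is.na(pm[1, 1])) {
          rel_cand$start[i] <- rel_cand$start[i] - nchar(pm[1, 1])
        }
        surf <- substr(text, rel_cand$start[i] + 1L, rel_cand$end[i])
        rel_cand$multiplicity[i] <- parse_multiplicity(surf)
      }
      rel_cand$surface <- substr(rep(text, nrow(rel_cand)),
                                 rel_cand$start + 1L, rel_cand$end)
      rel_cand$label <- "FAMILYMEMBER"
      rel_cand$class <- "FAMILYMEMBER"
      rel_cand$norm <- rel_cand$code
      rows[[length(rows) + 1]] <- rel_cand[, c("start", "end", "surface",
                                               "label", "class", "norm",
                                               "code", "degree", "sex",
                                               "side", "multiplicity")]
    }

    # onsets / deceased age
    ons_cand <- map_dfr(onset_comment_patterns(), function(p) {
      loc <- locate_within(text, p$pattern, lo, hi)
      if (nrow(loc) == 0) return(NULL)
      loc$label <- p$label
      loc$priority <- p$priority
      loc
    })
    ons_cand <- resolve_overlaps(ons_cand)
    if (nrow(ons_cand) > 0) {
      ons_cand$surface <- substr(rep(text, nrow(ons_cand)),
                                 ons_cand$start + 1L, ons_cand$end)
      # the matched pattern decides the subtype; parsing only fills bounds
      parsed <- map(seq_len(nrow(ons_cand)), function(i) {
        lab <- ons_cand$label[i]
        surf <- ons_cand$surface[i]
        num <- suppressWarnings(
          as.numeric(str_match(surf, "(\\d{1,3})")[, 2]))
        switch(lab,
               ONSET_AGE = list(kind = "AGE", lower = num, upper = num),
               ONSET_RANGE = parse_onset(surf),
               ONSET_PERIOD = list(kind = "PERIOD", lower = NA_real_,
                                   upper = NA_real_),
               ONSET_STRING = list(kind = "STRING", lower = NA_real_,
                                   upper = NA_real_),
               DECEASED_AGE = list(kind = "DECEASED", lower = num,
                                   upper = num))
      })
      ons_rows <- fast_tibble(
        start = ons_cand$start, end = ons_cand$end,
        surface = ons_cand$surface,
        label = ons_cand$label,
        class = ifelse(ons_cand$label == "DECEASED_AGE", "DECEASED",
                       "ONSET"),
        norm = ons_cand$surface,
        onset_kind = map_chr(parsed, "kind"),
        onset_lower = map_dbl_na(parsed, "lower"),
        onset_upper = map_dbl_na(parsed, "upper")
      )
      rows[[length(rows) + 1]] <- ons_rows
    }
  }

  out <- new_entities(rows)
  if (nrow(out) > 0) {
    out <- out[order(out$start, out$end), ]
    out$ent_id <- paste0("T", seq_len(nrow(out)))
    out$entry_id <- marked$entry_id
  }
  out
}

map_dbl_na <- function(x, field) {
  vapply(x, function(el) {
    v <- el[[field]]
    if (is.null(v) || length(v) == 0) NA_real_ else as.numeric(v)
  }, numeric(1))
}

#' Apply context rules
#'
#' Marks entities found inside `{{ }}` markers as structural, ignores
#' family members in exclusion contexts (e.g. "lives with her daughter"),
#' ignores onset/deceased mentions that describe the patient rather than the
#' relative ("died when pt was 5"), and sets the uncertainty flag on
#' condition entities whose segment contains an uncertainty cue.
#'
#' @param entities entity tibble from [match_lexicon()]
#' @param marked the `fhh_marked` the entities index into
#' @param config an [fhh_config()]
#' @return the entity tibble with features/statuses updated
#' @export
apply_context_rules <- function(entities, marked, config = fhh_config()) {
  if (nrow(entities) == 0) return(entities)
  lex <- config$lexicon
  text <- marked$text
  regions <- marked_regions(marked)
  com <- marked$spans[marked$spans$field == "comment", ]

  inside <- vapply(entities$start, function(s) {
    any(s >= regions$start & s < regions$end)
  }, logical(1))
  entities$is_structural <- entities$is_structural | inside

  segs <- split_sentences(marked)
  entities$seg_id <- vapply(entities$start, function(s) {
    segs$seg_id[which(s >= segs$start & s < segs$end)[1]]
  }, integer(1))

  window_before <- function(start, width = 24L) {
    lo <- max(com$start, start - width)
    substr(text, lo + 1L, start)
  }

  for (i in seq_len(nrow(entities))) {
    if (entities$is_structural[i]) next
    before <- str_to_lower(window_before(entities$start[i]))
    if (entities$class[i] == "FAMILYMEMBER" &&
        any(str_detect(before, lex$fm_exclusion))) {
      entities$status[i] <- "IGNORED"
      entities$ignore_reason[i] <- "exclusion_context"
    }
    if (entities$class[i] %in% c("ONSET", "DECEASED") &&
        any(str_detect(before, lex$onset_exclusion))) {
      entities$status[i] <- "IGNORED"
      entities$ignore_reason[i] <- "exclusion_context"
    }
  }

  # uncertainty cues scope over their sentence segment (comment text only)
  cue_pattern <- paste(lex$uncertainty_cues, collapse = "|")
  for (s in unique(entities$seg_id)) {
    seg <- segs[segs$seg_id == s, ]
    lo <- max(seg$start, com$start)
    hi <- min(seg$end, com$end)
    if (hi <= lo) next
    seg_comment <- substr(text, lo + 1L, hi)
    if (str_detect(str_to_lower(seg_comment), cue_pattern)) {
      hitrows <- entities$seg_id == s &
        entities$class %in% c("CANCER", "SYNDROME", "GENE_MUT")
      entities$uncertainty[hitrows] <- TRUE
      # a cue in the first segment also hedges the structured condition
      strcond <- entities$is_structural &
        entities$class %in% c("CANCER", "SYNDROME", "GENE_MUT")
      if (s == min(entities$seg_id, na.rm = TRUE)) {
        entities$uncertainty[strcond] <- TRUE
      }
    }
  }
  entities
}

#' Classify family-member entities
#'
#' Populates the normalized relative code, sex, degree and side. A
#' structural family member keeps the attributes of its coded value; a
#' comment-derived one inherits them from the matched lexicon term, with a
#' `maternal`/`paternal` cue word immediately before the mention (or a side
#' phrase just after it) overriding an unknown side.
#'
#' @param entities entity tibble after [apply_context_rules()]
#' @param marked the `fhh_marked`
#' @param config an [fhh_config()]
#' @return the entity tibble with family-member attributes populated
#' @export
classify_entities <- function(entities, marked, config = fhh_config()) {
  if (nrow(entities) == 0) return(entities)
  text <- marked$text
  fm <- which(entities$class == "FAMILYMEMBER" & !entities$is_structural)
  for (i in fm) {
    if (entities$side[i] != "UNKNOWN") next
    before <- str_to_lower(substr(text, max(1L, entities$start[i] - 12L),
                                  entities$start[i]))
    after <- str_to_lower(substr(text, entities$end[i] + 1L,
                                 min(nchar(text), entities$end[i] + 24L)))
    if (str_detect(before, "maternal\\s*$") ||
        str_detect(after, "^\\s*on\\s+(?:his|her|their\\s+)?\\s*mother'?s?\\s+side")) {
      entities$side[i] <- "MATERNAL"
    } else if (str_detect(before, "paternal\\s*$") ||
               str_detect(after, "^\\s*on\\s+(?:his|her|their\\s+)?\\s*father'?s?\\s+side")) {
      entities$side[i] <- "PATERNAL"
    }
  }
  entities
}

#' Run step 1 end to end
#'
#' Lexicon matching, context rules and classification over one marked entry.
#'
#' @param marked an `fhh_marked`
#' @param config an [fhh_config()]
#' @return an entity tibble
#' @export
extract_entities <- function(marked, config = fhh_config()) {
  entities <- match_lexicon(marked, config)
  entities <- apply_context_rules(entities, marked, config)
  classify_entities(entities, marked, config)
}
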