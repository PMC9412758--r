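#' Override structured conditions negated by the comment
#'
#' Comment terms in the condition-override lexicon (precancer, benign, cyst,
#' no cancer, ...) indicate that the coded condition is not an actual cancer
#' history; the structured condition entity, and any condition entity in the
#' same segment as the override term, is set to IGNORED. Override terms
#' inside `{{ }}` markers never fire (structured values are codes, not
#' narrative).
#'
#' @param entities entity tibble
#' @param marked the `fhh_marked`
#' @param config an [fhh_config()]
#' @return the entity tibble with statuses updated
#' @export
override_condition <- function(entities, marked, config = fhh_config()) {
  if (nrow(entities) == 0) return(entities)
  lex <- config$lexicon
  com <- marked$spans[marked$spans$field == "comment", ]
  if (!nzchar(com$value)) return(entities)
  pats <- vapply(lex$condition_overrides, term_pattern, character(1))
  hits <- bind_rows(lapply(pats, function(p) {
    locate_within(marked$text, p, com$start, com$end)
  }))
  if (nrow(hits) == 0) return(entities)
  segs <- split_sentences(marked)
  hit_segs <- unique(vapply(hits$start, function(s) {
    segs$seg_id[which(s >= segs$start & s < segs$end)[1]]
  }, integer(1)))
  is_cond <- entities$class %in% c("CANCER", "SYNDROME", "GENE_MUT")
  drop <- is_cond & (entities$is_structural | entities$seg_id %in% hit_segs)
  entities$status[drop] <- "IGNORED"
  entities$ignore_reason[drop] <- "condition_override"
  entities
}

active <- function(entities) entities$status == "ACTIVE"

ignore_rows <- function(entities, rows, reason) {
  entities$status[rows] <- "IGNORED"
  entities$ignore_reason[rows] <- reason
  entities
}

#' Reconcile structured and comment-derived entities
#'
#' Resolves conflicts between structural and comment-derived mentions with a
#' fixed, ordered rule set. Losing entities are set to IGNORED, never
#' deleted. In order:
#'
#' 0. A comment condition refines or corrects the structured condition: a
#'    specific cancer site in the comment supersedes a generic structured
#'    CANCER (refinement) or a different structured site (correction); a
#'    comment mention of the same site as the structured code is a duplicate
#'    and the structured entity is kept.
#' 1. A colorectal-cancer syndrome in the comment overrides a structured
#'    colon cancer.
#' 2. A comment onset range overrides a structured onset age.
#' 3. A comment onset period is ignored when a structured age exists.
#' 4. A comment onset string is ignored when a structured age exists.
#' 5. A deceased age with no structured onset infers an onset range from 0 to
#'    the deceased age (onset was before death); the deceased-age mention
#'    itself never links.
#' 6. A specific comment family member overrides the structured family
#'    member, unless a conjunction (and/also/&/+) immediately precedes it, in
#'    which case both stay active.
#' 7. A nonspecific side-only comment ("father side") keeps the structured
#'    family member and sets its side feature.
#' 8. A family member with multiplicity N expands to N instances.
#'
#' Reconciliation is idempotent and never creates new condition entities.
#'
#' @param entities entity tibble (classified)
#' @param marked the `fhh_marked`
#' @param config an [fhh_config()]
#' @return the entity tibble with statuses resolved and multiplicity expanded
#' @export
reconcile <- function(entities, marked, config = fhh_config()) {
  if (nrow(entities) == 0) return(entities)
  lex <- config$lexicon
  text <- marked$text

  is_cancer <- entities$class == "CANCER"
  str_cond <- entities$is_structural &
    entities$class %in% c("CANCER", "SYNDROME", "GENE_MUT")
  com_cancer <- !entities$is_structural & is_cancer

  # R0: comment cancer mention vs structured condition
  if (any(str_cond & active(entities)) &&
      any(com_cancer & active(entities))) {
    str_rows <- which(str_cond & active(entities) & is_cancer)
    for (i in str_rows) {
      com_rows <- which(com_cancer & active(entities))
      same <- com_rows[entities$norm[com_rows] == entities$norm[i]]
      if (length(same) > 0) {
        entities <- ignore_rows(entities, same, "duplicate_of_structured")
        # keep the structured entity, but let the comment duplicate pass on
        # an uncertainty hedge it picked up
        if (any(entities$uncertainty[same])) entities$uncertainty[i] <- TRUE
        next
      }
      specific <- com_rows[entities$norm[com_rows] != "CANCER"]
      if (length(specific) > 0) {
        reason <- if (entities$norm[i] == "CANCER") "refined_by_comment"
                  else "corrected_by_comment"
        entities <- ignore_rows(entities, i, reason)
      }
    }
  }

  # R1: structured colon cancer overridden by a colorectal syndrome
  syn <- which(!entities$is_structural & entities$class == "SYNDROME" &
                 entities$norm %in% lex$crc_syndromes & active(entities))
  if (length(syn) > 0) {
    colon <- which(entities$is_structural & entities$norm == "COLON" &
                     active(entities))
    entities <- ignore_rows(entities, colon, "syndrome_override")
  }

  str_onset_age <- entities$is_structural & entities$label == "ONSET_AGE"
  com_onset <- !entities$is_structural & entities$class == "ONSET"

  # R2: comment range overrides structured age
  if (any(str_onset_age & active(entities))) {
    rng <- which(com_onset & entities$onset_kind == "RANGE" &
                   active(entities))
    if (length(rng) > 0) {
      entities <- ignore_rows(entities, which(str_onset_age & active(entities)),
                              "range_override")
    }
  }

  # R2b: comment exact age corrects structured age
  if (any(str_onset_age & active(entities))) {
    age <- which(com_onset & entities$onset_kind == "AGE" & active(entities))
    if (length(age) > 0) {
      str_rows <- which(str_onset_age & active(entities))
      if (all(entities$onset_lower[age] == entities$onset_lower[str_rows][1])) {
        entities <- ignore_rows(entities, age, "duplicate_of_structured")
      } else {
        entities <- ignore_rows(entities, str_rows, "corrected_by_comment")
      }
    }
  }

  # R3/R4: comment period/string ignored when a structured age exists
  if (any(str_onset_age & active(entities))) {
    ps <- which(com_onset & entities$onset_kind %in% c("PERIOD", "STRING") &
                  active(entities))
    entities <- ignore_rows(entities, ps, "structured_age_preferred")
  }

  # R5: deceased age with no structured onset infers an onset range
  dec <- which(entities$class == "DECEASED" & active(entities))
  if (length(dec) > 0) {
    has_str_onset <- any(str_onset_age & active(entities))
    if (!has_str_onset && !any(entities$inferred)) {
      d <- dec[1]
      inferred <- new_entities(tibble(
        ent_id = paste0(entities$ent_id[d], "i"),
        entry_id = entities$entry_id[d],
        start = entities$start[d], end = entities$end[d],
        surface = entities$surface[d],
        label = "ONSET_RANGE", class = "ONSET", norm = entities$surface[d],
        onset_kind = "RANGE", onset_lower = 0,
        onset_upper = entities$onset_upper[d],
        inferred = TRUE, seg_id = entities$seg_id[d]))
      entities <- bind_rows(entities, inferred)
    }
    entities <- ignore_rows(entities, which(entities$class == "DECEASED" &
                                              active(entities)),
                            "deceased_consumed")
  }

  fm <- entities$class == "FAMILYMEMBER"
  str_fm <- fm & entities$is_structural
  com_fm <- fm & !entities$is_structural
  specific_fm <- com_fm & entities$code != "SIDE_ONLY"

  # R6: specific comment family member overrides the structured one, unless
  # conjunction-prefixed
  spec_rows <- which(specific_fm & active(entities))
  if (length(spec_rows) > 0 && any(str_fm & active(entities))) {
    com_span <- marked$spans[marked$spans$field == "comment", ]
    conj <- vapply(spec_rows, function(i) {
      lo <- max(com_span$start, entities$start[i] - 10L)
      before <- str_to_lower(substr(text, lo + 1L, entities$start[i]))
      str_detect(before, lex$conjunctions)
    }, logical(1))
    if (any(!conj)) {
      entities <- ignore_rows(entities, which(str_fm & active(entities)),
                              "corrected_by_comment")
    }
  }

  # R7: nonspecific side-only phrase decorates the structured family member
  side_rows <- which(com_fm & entities$code == "SIDE_ONLY" &
                       active(entities))
  if (length(side_rows) > 0) {
    str_rows <- which(str_fm & active(entities))
    for (i in str_rows) {
      if (entities$side[i] == "UNKNOWN") {
        entities$side[i] <- entities$side[side_rows[1]]
      }
    }
    entities <- ignore_rows(entities, side_rows, "side_feature")
  }

  # R8: multiplicity expansion
  expand <- which(fm & active(entities) & entities$multiplicity > 1L &
                    !entities$expanded)
  if (length(expand) > 0) {
    clones <- lapply(expand, function(i) {
      n <- entities$multiplicity[i]
      reps <- entities[rep(i, n), ]
      reps$instance <- seq_len(n)
      reps$expanded <- TRUE
      reps
    })
    entities <- bind_rows(entities[-expand, ], clones)
    entities <- entities[order(entities$start, entities$instance), ]
  }

  entities
}
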