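condition_relation_type <- c(CANCER = "FX_CANCER", SYNDROME = "FX_SYNDROME",
                             GENE_MUT = "FX_GENE_MUT")

assertions_proto <- tibble(
  patient_id = character(), entry_id = character(),
  relative_code = character(), degree = integer(), side = character(),
  sex = character(), condition = character(),
  condition_class = character(), onset_kind = character(),
  onset_lower = double(), onset_upper = double(), onset_raw = character(),
  onset_inferred = logical(), uncertain = logical(), count = integer(),
  relative_source = character(), condition_source = character(),
  onset_source = character())

empty_assertions <- function() assertions_proto

#' Link family members to conditions and onsets
#'
#' Step 3: within each sentence segment, every ACTIVE family-member instance
#' is linked to every ACTIVE condition entity in its scope (`FX_CANCER`,
#' `FX_SYNDROME`, `FX_GENE_MUT`) and to the ACTIVE onset in scope
#' (`FX_ONSET`). The scope of a condition is the comment family members of
#' its own segment plus the structured family member (comments routinely
#' rely on the structured relative); if that is empty, any active family
#' member of the entry. One relative with two cancers yields two condition
#' relations, one cancer with two relatives likewise. IGNORED entities never
#' participate. Conditions with no family member in scope are reported as
#' orphans in the `orphans` attribute of the result.
#'
#' @param entities reconciled entity tibble
#' @param segments segment tibble from [split_sentences()]
#' @return a relation tibble (`rel_id`, `type`, `source_id`,
#'   `source_instance`, `target_id`) with an `orphans` attribute
#' @export
link_relations <- function(entities, segments) {
  act <- entities[entities$status == "ACTIVE", ]
  fms <- act[act$class == "FAMILYMEMBER", ]
  conds <- act[act$class %in% names(condition_relation_type), ]
  onsets <- act[act$class == "ONSET", ]

  rels <- list()
  orphans <- character(0)

  fm_scope <- function(seg) {
    same_seg <- fms[!fms$is_structural & fms$seg_id == seg, ]
    scope <- bind_rows(same_seg, fms[fms$is_structural, ])
    if (nrow(scope) == 0) scope <- fms
    scope
  }

  if (nrow(conds) > 0) {
    for (ci in seq_len(nrow(conds))) {
      scope <- fm_scope(conds$seg_id[ci])
      if (nrow(scope) == 0) {
        orphans <- c(orphans, conds$ent_id[ci])
        next
      }
      rels[[length(rels) + 1]] <- fast_tibble(
        type = condition_relation_type[[conds$class[ci]]],
        source_id = scope$ent_id, source_instance = scope$instance,
        target_id = conds$ent_id[ci])
    }
  }

  if (nrow(fms) > 0 && nrow(onsets) > 0) {
    for (fi in seq_len(nrow(fms))) {
      cand <- onsets[onsets$seg_id == fms$seg_id[fi] & !onsets$is_structural |
                       onsets$is_structural, ]
      if (nrow(cand) == 0) cand <- onsets
      rels[[length(rels) + 1]] <- fast_tibble(
        type = "FX_ONSET",
        source_id = fms$ent_id[fi], source_instance = fms$instance[fi],
        target_id = cand$ent_id)
    }
  }

  out <- if (length(rels) > 0) bind_rows(rels) else
    tibble(type = character(), source_id = character(),
           source_instance = integer(), target_id = character())
  out <- distinct(out)
  out$rel_id <- if (nrow(out) > 0) paste0("R", seq_len(nrow(out)))
                else character(0)
  out <- out[, c("rel_id", "type", "source_id", "source_instance",
                 "target_id")]
  attr(out, "orphans") <- unique(orphans)
  out
}

#' Convert relations to normalized relative assertions
#'
#' One assertion per condition relation, carrying the linked onset (the one
#' sharing the condition's segment when several survive), side, sex, degree,
#' uncertainty and provenance. Expanded multiplicity instances of the same
#' family member with the same condition collapse into a single assertion
#' with the corresponding count.
#'
#' @param entities reconciled entity tibble
#' @param relations relation tibble from [link_relations()]
#' @param entry the originating single-row `fhh_entries` (for ids)
#' @param config an [fhh_config()]
#' @return an assertion tibble
#' @export
to_assertions <- function(entities, relations, entry,
                          config = fhh_config()) {
  empty <- empty_assertions()
  cond_rel <- relations[relations$type != "FX_ONSET", ]
  if (nrow(cond_rel) == 0) return(empty)
  onset_rel <- relations[relations$type == "FX_ONSET", ]
  ent <- function(id) entities[entities$ent_id == id, ][1, ]

  rows <- map_dfr(seq_len(nrow(cond_rel)), function(i) {
    f_id <- cond_rel$source_id[i]
    f_inst <- cond_rel$source_instance[i]
    f <- entities[entities$ent_id == f_id & entities$instance == f_inst, ][1, ]
    c_ <- ent(cond_rel$target_id[i])
    linked_onsets <- onset_rel[onset_rel$source_id == f_id &
                                 onset_rel$source_instance == f_inst, ]
    o <- NULL
    if (nrow(linked_onsets) > 0) {
      cands <- entities[entities$ent_id %in% linked_onsets$target_id, ]
      same_seg <- cands[cands$seg_id == c_$seg_id, ]
      o <- if (nrow(same_seg) > 0) same_seg[1, ]
           else if (any(cands$is_structural)) cands[cands$is_structural, ][1, ]
           else cands[1, ]
    }
    fast_tibble(
      patient_id = as.character(entry$patient_id)[1],
      entry_id = as.character(entry$entry_id)[1],
      fm_id = f_id, cond_id = c_$ent_id,
      relative_code = f$code, degree = f$degree, side = f$side, sex = f$sex,
      condition = c_$norm, condition_class = c_$class,
      onset_kind = if (is.null(o)) NA_character_ else o$onset_kind,
      onset_lower = if (is.null(o)) NA_real_ else o$onset_lower,
      onset_upper = if (is.null(o)) NA_real_ else o$onset_upper,
      onset_raw = if (is.null(o)) NA_character_ else o$surface,
      onset_inferred = if (is.null(o)) FALSE else isTRUE(o$inferred),
      uncertain = isTRUE(c_$uncertainty),
      relative_source = if (f$is_structural) "structured" else "comment",
      condition_source = if (c_$is_structural) "structured" else "comment",
      onset_source = if (is.null(o)) NA_character_
                     else if (o$is_structural) "structured"
                     else if (isTRUE(o$inferred)) "inferred" else "comment")
  })
  # collapse identical assertion rows (multiplicity instances) into counts
  rows$fm_id <- NULL
  rows$cond_id <- NULL
  key <- do.call(paste, c(lapply(rows, as.character), sep = "\x1f"))
  first <- !duplicated(key)
  out <- rows[first, ]
  out$count <- as.integer(tabulate(match(key, key[first]),
                                   nbins = sum(first)))
  out$degree <- as.integer(out$degree)
  out[, names(empty)]
}

#' Count condition relations
#'
#' Multiplicity-weighted count of assertions whose condition is in the given
#' set; used by the criteria that count affected relatives by relations
#' rather than by distinct persons.
#'
#' @param assertions an assertion tibble
#' @param condition_set character vector of normalized conditions
#' @return a non-negative integer
#' @export
count_condition_relations <- function(assertions, condition_set) {
  if (nrow(assertions) == 0) return(0L)
  as.integer(sum(assertions$count[assertions$condition %in% condition_set]))
}
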