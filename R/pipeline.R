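#' Annotate one FHH entry
#'
#' Runs the full extraction pipeline on a single entry: field concatenation,
#' sentence segmentation, lexicon matching with context rules, condition
#' override, reconciliation, relation linking and conversion to normalized
#' assertions.
#'
#' @param entry a single-row `fhh_entries` tibble
#' @param config an [fhh_config()]
#' @return a list of class `fhh_annotation` with elements `entry_id`,
#'   `marked`, `segments`, `entities`, `relations`, `assertions`, `orphans`
#' @export
annotate_entry <- function(entry, config = fhh_config()) {
  marked <- combine_fields(entry)
  marked$segments <- split_sentences(marked)
  segments <- marked$segments
  entities <- extract_entities(marked, config)
  entities <- override_condition(entities, marked, config)
  entities <- reconcile(entities, marked, config)
  relations <- link_relations(entities, segments)
  assertions <- to_assertions(entities, relations, entry, config)
  structure(list(
    entry_id = as.character(entry$entry_id)[1],
    marked = marked, segments = segments, entities = entities,
    relations = relations, assertions = assertions,
    orphans = attr(relations, "orphans")
  ), class = "fhh_annotation")
}

#' @export
print.fhh_annotation <- function(x, ...) {
  cat("<fhh_annotation> entry", x$entry_id, "\n")
  cat("  text: ", x$marked$text, "\n", sep = "")
  act <- x$entities[x$entities$status == "ACTIVE", ]
  cat("  entities:", nrow(act), "active /", nrow(x$entities), "total;",
      "relations:", nrow(x$relations), "\n")
  invisible(x)
}

#' Annotate a table of FHH entries
#'
#' @param entries an `fhh_entries` tibble
#' @param config an [fhh_config()]
#' @return a list of `fhh_annotation`, one per entry, named by entry id
#' @export
annotate_entries <- function(entries, config = fhh_config()) {
  out <- lapply(seq_len(nrow(entries)), function(i) {
    annotate_entry(entries[i, ], config)
  })
  names(out) <- entries$entry_id
  out
}

#' Extract normalized assertions from a table of FHH entries
#'
#' @param entries an `fhh_entries` tibble
#' @param config an [fhh_config()]
#' @return a combined assertion tibble
#' @export
extract_assertions <- function(entries, config = fhh_config()) {
  anns <- annotate_entries(entries, config)
  bind_rows(lapply(anns, function(a) a$assertions))
}

#' Relation keys of an annotation set
#'
#' Normalizes relations into the comparable form the evaluator scores: one
#' row per relation with the relation type, the normalized source
#' family-member code (with instance and side), and the normalized target
#' (condition norm, or onset kind with bounds), plus the uncertainty flag.
#'
#' @param annotations list of `fhh_annotation` (or a single one)
#' @return a relation-key tibble
#' @export
relation_keys <- function(annotations) {
  if (inherits(annotations, "fhh_annotation")) {
    annotations <- list(annotations)
  }
  map_dfr(annotations, function(a) {
    rel <- a$relations
    if (nrow(rel) == 0) return(NULL)
    e <- a$entities
    ent <- function(ids) e[match(ids, e$ent_id), ]
    src <- ent(rel$source_id)
    tgt <- ent(rel$target_id)
    fast_tibble(
      entry_id = a$entry_id,
      type = rel$type,
      source_code = src$code,
      source_instance = rel$source_instance,
      side = src$side,
      target_label = tgt$label,
      target_norm = ifelse(tgt$class == "ONSET",
                           onset_key(tgt), tgt$norm),
      uncertain = ifelse(rel$type == "FX_ONSET", FALSE, tgt$uncertainty))
  })
}

onset_key <- function(ent) {
  fmt <- function(x) ifelse(is.na(x), "", format(x, trim = TRUE))
  paste0(ent$onset_kind, "[", fmt(ent$onset_lower), ",",
         fmt(ent$onset_upper), "]")
}
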