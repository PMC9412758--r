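annotation_entity_fields <- c("ent_id", "entry_id", "start", "end",
                              "surface", "label", "class", "norm",
                              "is_structural", "uncertainty", "status",
                              "code", "side", "sex", "degree",
                              "multiplicity", "instance", "onset_kind",
                              "onset_lower", "onset_upper", "inferred",
                              "expanded", "ignore_reason", "seg_id")

#' Write annotations as line-delimited JSON records
#'
#' One record per line: entity records carry spans, labels, features and
#' statuses; relation records carry the type and the two argument ids. The
#' format round-trips through [read_annotations()] losslessly.
#'
#' @param entities entity tibble (may span several entries)
#' @param relations relation tibble
#' @param path output path
#' @return `path`, invisibly
#' @export
write_annotations <- function(entities, relations, path) {
  con <- tryCatch(file(path, open = "wt"),
                  error = function(e) abort(
                    paste0("cannot write ", path, ": ", conditionMessage(e)),
                    class = "fhh_io_error"))
  on.exit(close(con))
  if (nrow(entities) > 0) {
    for (i in seq_len(nrow(entities))) {
      rec <- c(list(record = "entity"),
               as.list(entities[i, intersect(annotation_entity_fields,
                                             names(entities))]))
      writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, null = "null",
                                  na = "null"), con)
    }
  }
  if (nrow(relations) > 0) {
    for (i in seq_len(nrow(relations))) {
      rec <- c(list(record = "relation"), as.list(relations[i, ]))
      writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, na = "null"), con)
    }
  }
  invisible(path)
}

#' Read annotations written by [write_annotations()]
#'
#' @param path path to a JSON-lines annotation file
#' @return a list with `entities` and `relations`
#' @export
read_annotations <- function(path) {
  lines <- readLines(path)
  recs <- lapply(lines, jsonlite::fromJSON)
  kinds <- vapply(recs, function(r) r$record %||% "", character(1))
  if (any(kinds == "")) {
    abort("annotation record without a 'record' field",
          class = "fhh_schema_error")
  }
  to_row <- function(r) {
    r$record <- NULL
    as_tibble(lapply(r, function(v) if (is.null(v)) NA else v))
  }
  entities <- new_entities(lapply(recs[kinds == "entity"], to_row))
  relations <- bind_rows(lapply(recs[kinds == "relation"], to_row))
  if (nrow(relations) == 0) {
    relations <- tibble(rel_id = character(), type = character(),
                        source_id = character(), source_instance = integer(),
                        target_id = character())
  }
  list(entities = entities, relations = relations)
}

# ---- Brat standoff ---------------------------------------------------------

#' Write Brat standoff annotations
#'
#' Writes the text to `txt_path` and T (entity), A (attribute) and R
#' (relation) lines to `ann_path`. Offsets are 0-based half-open, as in
#' Brat. Attributes cover the family-member code, side, sex, uncertainty,
#' structural flag, status and multiplicity.
#'
#' @param entities entity tibble for one text
#' @param relations relation tibble
#' @param text the annotated text (e.g. `marked$text`)
#' @param ann_path,txt_path output paths
#' @return `ann_path`, invisibly
#' @export
write_brat_standoff <- function(entities, relations, text, ann_path,
                                txt_path) {
  writeLines(text, txt_path, useBytes = TRUE)
  lines <- character(0)
  aid <- 0L
  attr_line <- function(name, tid, value = NULL) {
    aid <<- aid + 1L
    if (is.null(value)) sprintf("A%d\t%s %s", aid, name, tid)
    else sprintf("A%d\t%s %s %s", aid, name, tid, value)
  }
  base <- entities[entities$instance == 1L, ]
  for (i in seq_len(nrow(base))) {
    e <- base[i, ]
    lines <- c(lines, sprintf("%s\t%s %d %d\t%s", e$ent_id, e$label,
                              e$start, e$end, e$surface))
    if (isTRUE(e$is_structural)) lines <- c(lines,
                                            attr_line("STRUCTURAL", e$ent_id))
    if (isTRUE(e$uncertainty)) lines <- c(lines,
                                          attr_line("UNCERTAINTY", e$ent_id))
    if (!is.na(e$code)) lines <- c(lines, attr_line("CODE", e$ent_id,
                                                    e$code))
    if (!is.na(e$side) && e$side != "UNKNOWN") {
      lines <- c(lines, attr_line("SIDE", e$ent_id, e$side))
    }
    if (!is.na(e$sex) && e$sex != "UNKNOWN") {
      lines <- c(lines, attr_line("SEX", e$ent_id, e$sex))
    }
    if (e$status != "ACTIVE") lines <- c(lines, attr_line("STATUS", e$ent_id,
                                                          e$status))
    if (e$multiplicity > 1L) {
      lines <- c(lines, attr_line("MULTIPLICITY", e$ent_id,
                                  e$multiplicity))
    }
  }
  rel <- distinct(relations[, c("rel_id", "type", "source_id", "target_id")])
  for (i in seq_len(nrow(rel))) {
    lines <- c(lines, sprintf("%s\t%s Arg1:%s Arg2:%s", rel$rel_id[i],
                              rel$type[i], rel$source_id[i],
                              rel$target_id[i]))
  }
  writeLines(lines, ann_path, useBytes = TRUE)
  invisible(ann_path)
}

#' Read Brat standoff annotations
#'
#' Reconstructs entities and relations from T/A/R lines; attribute lines
#' populate the entity features. A relation argument that references an
#' unknown entity id raises a parse error naming the line number.
#'
#' @param ann_path path to the `.ann` file
#' @param txt_path path to the `.txt` file
#' @return a list with `text`, `entities`, `relations`
#' @export
read_brat_standoff <- function(ann_path, txt_path) {
  text <- paste(readLines(txt_path, warn = FALSE), collapse = "\n")
  lines <- readLines(ann_path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  ents <- list(); rels <- list(); attrs <- list()
  for (ln in seq_along(lines)) {
    line <- lines[ln]
    kind <- substr(line, 1, 1)
    parts <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (kind == "T") {
      head_parts <- strsplit(parts[2], " ", fixed = TRUE)[[1]]
      if (length(head_parts) < 3 || length(parts) < 2) {
        abort(paste0("malformed T line ", ln), class = "fhh_parse_error")
      }
      start <- as.integer(head_parts[2]); end <- as.integer(head_parts[3])
      if (is.na(start) || is.na(end) || start < 0 || end > nchar(text) ||
          end <= start) {
        abort(paste0("invalid offsets on line ", ln),
              class = "fhh_parse_error")
      }
      ents[[length(ents) + 1]] <- tibble(
        ent_id = parts[1], label = head_parts[1],
        start = start, end = end,
        surface = if (length(parts) >= 3) parts[3]
                  else substr(text, start + 1L, end))
    } else if (kind == "A") {
      a <- strsplit(parts[2], " ", fixed = TRUE)[[1]]
      attrs[[length(attrs) + 1]] <- list(name = a[1], tid = a[2],
                                         value = if (length(a) >= 3) a[3]
                                                 else NA_character_,
                                         line = ln)
    } else if (kind == "R") {
      m <- str_match(parts[2], "^(\\S+) Arg1:(\\S+) Arg2:(\\S+)$")
      if (is.na(m[1, 1])) {
        abort(paste0("malformed R line ", ln), class = "fhh_parse_error")
      }
      rels[[length(rels) + 1]] <- tibble(rel_id = parts[1], type = m[1, 2],
                                         source_id = m[1, 3],
                                         target_id = m[1, 4], line = ln)
    }
  }
  entities <- new_entities(ents)
  if (nrow(entities) > 0) {
    entities$class <- ifelse(
      entities$label == "FAMILYMEMBER", "FAMILYMEMBER",
      ifelse(entities$label == "SYNDROME", "SYNDROME",
      ifelse(entities$label == "GENE_MUT", "GENE_MUT",
      ifelse(entities$label == "DECEASED_AGE", "DECEASED",
      ifelse(grepl("^ONSET_", entities$label), "ONSET", "CANCER")))))
  }
  for (a in attrs) {
    i <- which(entities$ent_id == a$tid)
    if (length(i) == 0) {
      abort(paste0("attribute references unknown entity on line ", a$line),
            class = "fhh_parse_error")
    }
    switch(a$name,
           STRUCTURAL = { entities$is_structural[i] <- TRUE },
           UNCERTAINTY = { entities$uncertainty[i] <- TRUE },
           CODE = { entities$code[i] <- a$value
                    entities$norm[i] <- a$value },
           SIDE = { entities$side[i] <- a$value },
           SEX = { entities$sex[i] <- a$value },
           STATUS = { entities$status[i] <- a$value },
           MULTIPLICITY = {
             entities$multiplicity[i] <- as.integer(a$value)
           },
           NULL)
  }
  relations <- bind_rows(rels)
  if (nrow(relations) > 0) {
    dangling <- !(relations$source_id %in% entities$ent_id) |
      !(relations$target_id %in% entities$ent_id)
    if (any(dangling)) {
      abort(paste0("dangling relation argument on line ",
                   paste(relations$line[dangling], collapse = ", ")),
            class = "fhh_parse_error")
    }
    relations$source_instance <- 1L
    relations <- relations[, c("rel_id", "type", "source_id",
                               "source_instance", "target_id")]
  } else {
    relations <- tibble(rel_id = character(), type = character(),
                        source_id = character(), source_instance = integer(),
                        target_id = character())
  }
  list(text = text, entities = entities, relations = relations)
}

# ---- FHIR-style family member history export -------------------------------

#' Export assertions as FHIR-style FamilyMemberHistory records
#'
#' One FamilyMemberHistory-compatible record per assertion; an assertion
#' with count N emits N records (one per relative instance). The onset is an
#' `onsetAge` for exact ages and an `onsetRange` for ranges; uncertainty is
#' carried as a boolean extension rather than dropped, so both uncertainty
#' policies remain computable downstream.
#'
#' @param assertions an assertion tibble
#' @param patient a patient profile (for the subject reference)
#' @param path output JSON path
#' @return `path`, invisibly
#' @export
export_family_history <- function(assertions, patient, path) {
  records <- list()
  if (nrow(assertions) > 0) {
    for (i in seq_len(nrow(assertions))) {
      a <- assertions[i, ]
      for (k in seq_len(a$count)) {
        rec <- list(
          resourceType = "FamilyMemberHistory",
          status = "completed",
          patient = list(reference = paste0("Patient/",
                                            patient$patient_id)),
          relationship = list(text = str_to_lower(gsub("_", " ",
                                                       a$relative_code))),
          sex = if (!is.na(a$sex) && a$sex != "UNKNOWN") {
            list(text = str_to_lower(a$sex))
          },
          condition = list(list(
            code = list(text = condition_display(a$condition,
                                                 a$condition_class)))),
          extension = list(
            list(url = "uncertainty", valueBoolean = isTRUE(a$uncertain)),
            list(url = "side-of-family",
                 valueString = ifelse(is.na(a$side), "UNKNOWN", a$side)))
        )
        if (!is.na(a$onset_kind) && a$onset_kind == "AGE") {
          rec$condition[[1]]$onsetAge <- list(value = a$onset_lower,
                                              unit = "years")
        } else if (!is.na(a$onset_kind) && a$onset_kind == "RANGE") {
          rec$condition[[1]]$onsetRange <- list(
            low = list(value = a$onset_lower, unit = "years"),
            high = list(value = a$onset_upper, unit = "years"))
        } else if (!is.na(a$onset_kind)) {
          rec$condition[[1]]$onsetString <- a$onset_raw
        }
        records[[length(records) + 1]] <- rec
      }
    }
  }
  bundle <- list(resourceType = "Bundle", type = "collection",
                 entry = lapply(records, function(r) list(resource = r)))
  jsonlite::write_json(bundle, path, auto_unbox = TRUE, null = "null",
                       pretty = TRUE)
  invisible(path)
}

condition_display <- function(norm, class) {
  if (is.na(class)) return(norm)
  if (class == "CANCER") {
    if (norm == "CANCER") "cancer"
    else paste(str_to_lower(gsub("_", " ", norm)), "cancer")
  } else if (class == "SYNDROME") {
    paste(gsub("_", "-", norm), "syndrome")
  } else {
    norm
  }
}
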