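#' Concatenate structured fields and comment into marked text
#'
#' The four fields of an entry are joined with single spaces in the order
#' condition, comment, relative, onset, with each structured value wrapped in
#' double curly brackets so downstream rules can tell structured values from
#' narrative. A missing structured value renders as an empty marker `{{}}`.
#' Character offsets are 0-based and half-open.
#'
#' @param entry a single-row `fhh_entries` tibble (or list with the same
#'   fields)
#' @return an object of class `fhh_marked`: list with `text` and `spans`, a
#'   tibble mapping each region to its originating field (`start`/`end` are
#'   the outer span including brackets, `value_start`/`value_end` the inner
#'   value span)
#' @export
combine_fields <- function(entry) {
  fmt <- function(x) if (is.null(x) || is.na(x)) "" else as.character(x)
  cond <- fmt(entry$condition_code)
  rel <- fmt(entry$relative_code)
  onset <- fmt(entry$onset_age)
  comment <- fmt(entry$comment)

  pieces <- c(paste0("{{", cond, "}}"), comment, paste0("{{", rel, "}}"),
              paste0("{{", onset, "}}"))
  text <- paste(pieces, collapse = " ")

  starts <- cumsum(c(0L, nchar(pieces[-4]) + 1L))
  fields <- c("condition_code", "comment", "relative_code", "onset_age")
  marker <- fields != "comment"
  spans <- fast_tibble(
    field = fields,
    start = starts,
    end = starts + nchar(pieces),
    value = c(cond, comment, rel, onset),
    value_start = starts + ifelse(marker, 2L, 0L),
    value_end = starts + nchar(pieces) - ifelse(marker, 2L, 0L))
  structure(list(text = text, spans = spans,
                 entry_id = if (!is.null(entry$entry_id)) {
                   as.character(entry$entry_id)[1]
                 } else NA_character_),
            class = "fhh_marked")
}

#' @export
print.fhh_marked <- function(x, ...) {
  cat("<fhh_marked> ", x$text, "\n", sep = "")
  invisible(x)
}

#' Recover the comment from marked text
#'
#' Strips the three structured-field markers (and their values) from the
#' marked text, returning the comment verbatim.
#'
#' @param marked an `fhh_marked`
#' @return the comment string
#' @export
strip_markers <- function(marked) {
  com <- marked$spans[marked$spans$field == "comment", ]
  substr(marked$text, com$start + 1L, com$end)
}

marked_regions <- function(marked) {
  marked$spans[marked$spans$field != "comment", ]
}

# abbreviations whose trailing period never ends a sentence
sentence_abbrev <- c("dx", "ca", "yr", "yrs", "dr", "mo", "approx", "e.g",
                     "i.e")

#' Split marked text into sentence segments
#'
#' Telegraphic comments are split on `". "`, `";"` and newlines only, never
#' inside a `{{ }}` marker and never after a short list of clinical
#' abbreviations (dx., ca., yr., ...). Segments are contiguous and cover the
#' whole text, so the total character count is preserved.
#'
#' @param marked an `fhh_marked`
#' @return a tibble with `seg_id`, `start`, `end` (0-based half-open) and
#'   `text`
#' @export
split_sentences <- function(marked) {
  if (!is.null(marked$segments)) return(marked$segments)
  text <- marked$text
  n <- nchar(text)
  locs <- str_locate_all(text, "\\.\\s+|;\\s*|\\n+")[[1]]
  regions <- marked_regions(marked)
  boundaries <- integer(0)
  if (nrow(locs) > 0) {
    for (i in seq_len(nrow(locs))) {
      s0 <- locs[i, 1] - 1L # 0-based start of the punctuation
      e0 <- locs[i, 2]      # 0-based end (exclusive) of the separator
      inside <- any(s0 >= regions$start & s0 < regions$end)
      if (inside) next
      if (substr(text, s0 + 1L, s0 + 1L) == ".") {
        before <- str_to_lower(substr(text, max(1L, s0 - 9L), s0))
        word <- str_match(before, "([a-z.]+)$")[, 2]
        if (!is.na(word) && word %in% sentence_abbrev) next
      }
      if (e0 < n) boundaries <- c(boundaries, e0)
    }
  }
  starts <- unname(c(0L, boundaries))
  ends <- unname(c(boundaries, n))
  fast_tibble(seg_id = seq_along(starts), start = starts, end = ends,
              text = substr(rep(text, length(starts)), starts + 1L, ends))
}
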