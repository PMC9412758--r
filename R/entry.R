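#' Construct family health history entries
#'
#' One row per FHH assertion as stored in the EHR FHH section: a coded
#' condition, a coded relative, an integer age of onset and a free-text
#' comment. Any structured field may be missing; at least one of the
#' condition code, relative code or comment must be present.
#'
#' @param patient_id,entry_id opaque identifiers (non-empty patient id)
#' @param condition_code coded condition (e.g. `"CANCER, BREAST"`) or `NA`
#' @param relative_code coded relative (e.g. `"AUNT"`) or `NA`
#' @param onset_age integer age of onset in years (0--120) or `NA`
#' @param comment free-text comment, possibly empty
#' @param entry_date entry date (character or Date) or `NA`
#' @return a tibble of class `fhh_entries`, one row per entry
#' @export
fhh_entry <- function(patient_id, entry_id,
                      condition_code = NA_character_,
                      relative_code = NA_character_,
                      onset_age = NA_integer_,
                      comment = "",
                      entry_date = NA_character_) {
  out <- tibble(
    patient_id = as.character(patient_id),
    entry_id = as.character(entry_id),
    condition_code = as.character(condition_code),
    relative_code = as.character(relative_code),
    onset_age = as.integer(onset_age),
    comment = ifelse(is.na(comment), "", as.character(comment)),
    entry_date = as.character(entry_date)
  )
  validate_entries(out)
  class(out) <- c("fhh_entries", class(out))
  out
}

validate_entries <- function(entries) {
  bad_pid <- is_blank(entries$patient_id)
  if (any(bad_pid)) {
    abort("patient_id must be non-empty", class = "fhh_schema_error")
  }
  age <- entries$onset_age
  bad_age <- !is.na(age) & (age < 0 | age > 120)
  if (any(bad_age)) {
    abort(paste0("onset_age out of [0, 120] in entries: ",
                 paste(entries$entry_id[bad_age], collapse = ", ")),
          class = "fhh_schema_error")
  }
  empty <- is_blank(entries$condition_code) & is_blank(entries$relative_code) &
    is_blank(entries$comment)
  if (any(empty)) {
    abort(paste0("entry has neither condition code, relative code nor ",
                 "comment: ", paste(entries$entry_id[empty], collapse = ", ")),
          class = "fhh_schema_error")
  }
  invisible(entries)
}

fhh_required_columns <- c("patient_id", "entry_id", "condition_code",
                          "relative_code", "age_of_onset", "comment",
                          "entry_date")

#' Read a delimited FHH table
#'
#' Comma-delimited with header by default (`delim = "\t"` for tab-delimited).
#' Required columns: `patient_id`, `entry_id`, `condition_code`,
#' `relative_code`, `age_of_onset`, `comment`, `entry_date`. Blank cells
#' become `NA`; row order is preserved. Rows whose `age_of_onset` cannot be
#' parsed as an integer are kept with a missing onset and reported in a
#' single warning listing the offending entry ids.
#'
#' @param path path to the delimited file
#' @param delim field delimiter, `","` or `"\t"`
#' @return an `fhh_entries` tibble
#' @export
read_fhh_table <- function(path, delim = ",") {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "fhh_io_error")
  }
  raw <- read.csv(path, sep = delim, colClasses = "character",
                  check.names = FALSE, na.strings = NULL)
  missing <- setdiff(fhh_required_columns, names(raw))
  if (length(missing) > 0) {
    abort(paste0("missing required column(s): ",
                 paste(missing, collapse = ", ")),
          class = "fhh_schema_error")
  }
  if (nrow(raw) == 0) {
    return(fhh_entry(character(), character()))
  }
  blank_to_na <- function(x) ifelse(is_blank(x), NA_character_, trimws(x))
  onset_raw <- blank_to_na(raw$age_of_onset)
  onset <- suppressWarnings(as.integer(onset_raw))
  bad <- !is.na(onset_raw) & is.na(onset)
  if (any(bad)) {
    warn(paste0("unparseable age_of_onset in ", sum(bad), " row(s): ",
                paste(raw$entry_id[bad], collapse = ", ")))
  }
  fhh_entry(
    patient_id = trimws(raw$patient_id),
    entry_id = trimws(raw$entry_id),
    condition_code = blank_to_na(raw$condition_code),
    relative_code = blank_to_na(raw$relative_code),
    onset_age = onset,
    comment = ifelse(is_blank(raw$comment), "", raw$comment),
    entry_date = blank_to_na(raw$entry_date)
  )
}

#' Write an FHH table
#'
#' Inverse of [read_fhh_table()].
#'
#' @param entries an `fhh_entries` tibble
#' @param path output path
#' @param delim field delimiter
#' @return `path`, invisibly
#' @export
write_fhh_table <- function(entries, path, delim = ",") {
  out <- data.frame(
    patient_id = entries$patient_id,
    entry_id = entries$entry_id,
    condition_code = ifelse(is.na(entries$condition_code), "",
                            entries$condition_code),
    relative_code = ifelse(is.na(entries$relative_code), "",
                           entries$relative_code),
    age_of_onset = ifelse(is.na(entries$onset_age), "",
                          as.character(entries$onset_age)),
    comment = entries$comment,
    entry_date = ifelse(is.na(entries$entry_date), "", entries$entry_date),
    check.names = FALSE
  )
  utils::write.table(out, path, sep = delim, row.names = FALSE,
                     qmethod = "double", col.names = TRUE, quote = TRUE)
  invisible(path)
}

#' Assemble patient profiles
#'
#' Groups FHH entries by patient and attaches optional metadata (age, sex,
#' Ashkenazi Jewish flag) used by the criteria engine.
#'
#' @param entries an `fhh_entries` tibble
#' @param patients optional tibble with columns `patient_id` and any of
#'   `age`, `sex`, `ashkenazi_jewish`
#' @return a list of profiles, each a list with `patient_id`, `age`, `sex`,
#'   `ashkenazi_jewish` and `entries`
#' @export
patient_profiles <- function(entries, patients = NULL) {
  ids <- unique(entries$patient_id)
  if (!is.null(patients)) ids <- union(ids, patients$patient_id)
  lapply(ids, function(pid) {
    meta <- if (!is.null(patients)) patients[patients$patient_id == pid, ]
            else NULL
    get1 <- function(col, default) {
      if (!is.null(meta) && nrow(meta) > 0 && col %in% names(meta)) {
        meta[[col]][1]
      } else default
    }
    structure(list(
      patient_id = pid,
      age = get1("age", NA_real_),
      sex = get1("sex", NA_character_),
      ashkenazi_jewish = get1("ashkenazi_jewish", NA),
      entries = entries[entries$patient_id == pid, ]
    ), class = "fhh_patient")
  })
}

#' Read a patient metadata table
#'
#' @param path CSV with columns `patient_id` and optionally `age`, `sex`,
#'   `ashkenazi_jewish`
#' @return a tibble
#' @export
read_patient_table <- function(path) {
  raw <- as_tibble(read.csv(path, stringsAsFactors = FALSE))
  if (!"patient_id" %in% names(raw)) {
    abort("missing required column(s): patient_id",
          class = "fhh_schema_error")
  }
  raw$patient_id <- as.character(raw$patient_id)
  if ("ashkenazi_jewish" %in% names(raw)) {
    raw$ashkenazi_jewish <- as.logical(raw$ashkenazi_jewish)
  }
  raw
}
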