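# Shared fixtures: entries are built in code, never stored on disk.

entry1 <- function(condition = NA, relative = NA, onset = NA, comment = "",
                   pid = "P1", eid = "E1") {
  fhh_entry(pid, eid, condition, relative, onset, comment)
}

# the worked single-entry example: generic coded cancer, coded aunt, no
# onset, telegraphic comment carrying site, true relative and onset
worked_entry <- function() {
  entry1("CANCER", "AUNT", NA, "Breast, great-aunt, dx at age of 52")
}

make_assertion <- function(relative_code, condition,
                           condition_class = "CANCER",
                           degree = NA_integer_, side = "UNKNOWN",
                           sex = "UNKNOWN", onset_kind = NA_character_,
                           onset_lower = NA_real_, onset_upper = NA_real_,
                           uncertain = FALSE, count = 1L,
                           onset_inferred = FALSE,
                           condition_source = "structured",
                           patient_id = "P1", entry_id = "E1") {
  cfg <- fhh_config()
  if (is.na(degree)) degree <- degree_of(relative_code, cfg)
  tibble::tibble(
    patient_id = patient_id, entry_id = entry_id,
    relative_code = relative_code, degree = as.integer(degree),
    side = side, sex = sex, condition = condition,
    condition_class = condition_class, onset_kind = onset_kind,
    onset_lower = onset_lower, onset_upper = onset_upper,
    onset_raw = NA_character_, onset_inferred = onset_inferred,
    uncertain = uncertain, count = as.integer(count),
    relative_source = "structured", condition_source = condition_source,
    onset_source = NA_character_)
}

profile1 <- function(assertions = NULL, ashkenazi = NA, pid = "P1") {
  structure(list(patient_id = pid, age = 40, sex = "FEMALE",
                 ashkenazi_jewish = ashkenazi,
                 entries = entry1("CANCER", "AUNT")), class = "fhh_patient")
}

small_corpus <- function(n = 60, seed = 11, ...) {
  generate_corpus(sim_params(n_patients = n, seed = seed, ...))
}
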