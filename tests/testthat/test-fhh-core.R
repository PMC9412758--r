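test_that("read_fhh_table parses rows, blanks and bad onsets", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "patient_id,entry_id,condition_code,relative_code,age_of_onset,comment,entry_date",
    'P1,E1,CANCER,AUNT,,"Breast, great-aunt, dx at age of 52",2019-01-02',
    'P1,E2,"CANCER, BREAST",MOTHER,52,,2019-01-03',
    "P2,E3,DIABETES,MOTHER,abc,insulin dependent,"),
    path)
  expect_warning(entries <- read_fhh_table(path), "E3")
  expect_equal(nrow(entries), 3)
  expect_true(is.na(entries$onset_age[1]))
  expect_equal(entries$comment[1], "Breast, great-aunt, dx at age of 52")
  expect_equal(entries$onset_age[2], 52L)
  expect_true(is.na(entries$onset_age[3]))
  expect_equal(entries$entry_id, c("E1", "E2", "E3"))
})

test_that("read_fhh_table reports missing columns and handles empty files", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines("patient_id,entry_id,condition_code", path)
  expect_error(read_fhh_table(path), "relative_code",
               class = "fhh_schema_error")
  path2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(paste(c("patient_id", "entry_id", "condition_code",
                     "relative_code", "age_of_onset", "comment",
                     "entry_date"), collapse = ","), path2)
  expect_equal(nrow(read_fhh_table(path2)), 0)
})

test_that("fhh table writer round-trips entries", {
  corpus <- small_corpus(15, seed = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_fhh_table(corpus$entries, path)
  back <- read_fhh_table(path)
  cols <- c("patient_id", "entry_id", "condition_code", "relative_code",
            "onset_age", "comment")
  expect_equal(as.data.frame(back[, cols]),
               as.data.frame(corpus$entries[, cols]))
})

test_that("entry invariants are enforced", {
  expect_error(fhh_entry("", "E1", "CANCER"), class = "fhh_schema_error")
  expect_error(fhh_entry("P1", "E1", "CANCER", onset_age = 130),
               class = "fhh_schema_error")
  expect_error(fhh_entry("P1", "E1", NA, NA, NA, ""),
               class = "fhh_schema_error")
})

test_that("annotation records round-trip through the line format", {
  ann <- annotate_entry(worked_entry())
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_annotations(ann$entities, ann$relations, path)
  back <- read_annotations(path)
  expect_equal(nrow(back$entities), nrow(ann$entities))
  keep <- c("ent_id", "start", "end", "surface", "label", "norm",
            "is_structural", "uncertainty", "status", "side", "sex",
            "multiplicity", "instance", "onset_kind", "onset_lower",
            "onset_upper")
  expect_equal(as.data.frame(back$entities[, keep]),
               as.data.frame(ann$entities[, keep]))
  expect_equal(as.data.frame(back$relations[, names(ann$relations)]),
               as.data.frame(ann$relations), ignore_attr = TRUE)
})

test_that("writing empty annotations yields a zero-record file", {
  path <- withr::local_tempfile(fileext = ".jsonl")
  ann <- annotate_entry(entry1("DIABETES", "MOTHER"))
  write_annotations(ann$entities[0, ], ann$relations[0, ], path)
  expect_equal(length(readLines(path)), 0)
})

test_that("brat standoff round-trips entities, features and relations", {
  ann <- annotate_entry(worked_entry())
  ann_path <- withr::local_tempfile(fileext = ".ann")
  txt_path <- withr::local_tempfile(fileext = ".txt")
  write_brat_standoff(ann$entities, ann$relations, ann$marked$text,
                      ann_path, txt_path)
  back <- read_brat_standoff(ann_path, txt_path)
  expect_equal(back$text, ann$marked$text)
  keep <- c("ent_id", "start", "end", "surface", "label", "is_structural",
            "uncertainty", "status", "side")
  base <- ann$entities[ann$entities$instance == 1L, ]
  expect_equal(as.data.frame(back$entities[, keep]),
               as.data.frame(base[, keep]))
  expect_setequal(paste(back$relations$type, back$relations$source_id,
                        back$relations$target_id),
                  paste(ann$relations$type, ann$relations$source_id,
                        ann$relations$target_id))
})

test_that("brat reader reports dangling relation arguments by line", {
  ann_path <- withr::local_tempfile(fileext = ".ann")
  txt_path <- withr::local_tempfile(fileext = ".txt")
  writeLines("great-aunt had breast cancer", txt_path)
  writeLines(c("T1\tFAMILYMEMBER 0 10\tgreat-aunt",
               "R1\tFX_CANCER Arg1:T1 Arg2:T9"), ann_path)
  expect_error(read_brat_standoff(ann_path, txt_path), "line 2",
               class = "fhh_parse_error")
})

test_that("family history export emits one record per relative instance", {
  ann <- annotate_entry(worked_entry())
  path <- withr::local_tempfile(fileext = ".json")
  export_family_history(ann$assertions, profile1(), path)
  bundle <- jsonlite::read_json(path)
  expect_equal(length(bundle$entry), 1)
  rec <- bundle$entry[[1]]$resource
  expect_equal(rec$relationship$text, "great aunt")
  expect_equal(rec$condition[[1]]$code$text, "breast cancer")
  expect_equal(rec$condition[[1]]$onsetAge$value, 52)

  counted <- make_assertion("SISTER", "BREAST", count = 2,
                            onset_kind = "AGE", onset_lower = 42,
                            onset_upper = 42)
  export_family_history(counted, profile1(), path)
  bundle2 <- jsonlite::read_json(path)
  expect_equal(length(bundle2$entry), 2)

  export_family_history(counted[0, ], profile1(), path)
  expect_equal(length(jsonlite::read_json(path)$entry), 0)
})

test_that("pipeline entities satisfy the span/multiplicity invariants", {
  corpus <- small_corpus(25, seed = 5)
  anns <- annotate_entries(corpus$entries)
  for (a in anns) {
    expect_no_error(validate_entities(a$entities, a$marked))
  }
})

test_that("lexicon round-trips through its CSV directory format", {
  dir <- withr::local_tempdir()
  lex <- default_lexicon()
  write_lexicon(lex, dir)
  back <- read_lexicon(dir)
  expect_equal(as.data.frame(back$conditions), as.data.frame(lex$conditions))
  expect_equal(as.data.frame(back$relatives), as.data.frame(lex$relatives))
  expect_equal(back$number_words, lex$number_words)
  expect_equal(back$crc_syndromes, lex$crc_syndromes)
})
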