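# fhhscreen

Rule-based extraction of family health history (FHH) from the dedicated FHH
section of an electronic health record, and screening of the extracted
history against NCCN family-history criteria for genetic testing of
hereditary breast/ovarian and colorectal cancers.

## The problem

EHR FHH sections store one assertion per row: a coded condition (e.g.
`CANCER`), a coded relative (e.g. `AUNT`), an integer age of onset, and a
free-text comment. Clinicians put the detail that the picklists cannot
express into the comment — the cancer site ("Breast"), the true relative
("great-aunt", which the picklist lacks), an approximate onset ("dx in her
30s"), counts ("2× sisters"), sides of the family ("father side"), hedges
("possible"), and corrections ("precancer"). A screening algorithm that
reads only the structured fields misses or mis-codes these patients.

`fhhscreen` concatenates the structured values and the comment into one
string, marking structured values with double curly brackets:

```
{{CANCER}} Breast, great-aunt, dx at age of 52 {{AUNT}} {{}}
```

and then runs three rule-based steps:

1. **Entity extraction** — lexicon matching (cancer sites and synonyms,
   cancer syndromes, pathogenic genes, relatives, onset phrase patterns)
   with context rules: mentions inside `{{ }}` are flagged `is_structural`,
   irrelevant mentions ("lives with her daughter") are ignored, and
   uncertainty cues set a feature on the conditions they govern.
2. **Entity reconciliation** — eight ordered heuristics resolve conflicts
   between structured and comment-derived mentions (a comment onset range
   overrides a structured age; a specific comment relative replaces the
   coded one unless a conjunction precedes it; "2× sisters" expands to two
   family-member instances; ...). Losers are marked IGNORED, never deleted.
3. **Relation identification** — every ACTIVE family member is linked to the
   ACTIVE conditions and onset in its scope (`FX_CANCER`, `FX_SYNDROME`,
   `FX_GENE_MUT`, `FX_ONSET`); relation counts, not distinct persons, feed
   the criteria that count affected relatives.

The normalized output (relative, degree, side, sex, condition, onset,
uncertainty, count) drives a criteria engine implementing the NCCN
family-history criteria for unaffected patients: seven breast/ovarian
criteria (BO1–BO7) and four colorectal criteria (C1–C4), evaluable in a
structured-only or NLP-augmented mode and under an include- or
exclude-uncertainty policy.

A synthetic-corpus generator (`generate_corpus()`) emulates the entry
structure and comment phenomena above with constructive gold annotations,
and the evaluator scores relation extraction and patient eligibility with
micro-averaged precision/recall/F1 and percentile-bootstrap confidence
intervals.

## Worked example

```r
library(fhhscreen)

entry <- fhh_entry("P1", "E1",
                   condition_code = "CANCER", relative_code = "AUNT",
                   onset_age = NA,
                   comment = "Breast, great-aunt, dx at age of 52")
ann <- annotate_entry(entry)
ann
#> <fhh_annotation> entry E1
#>   text: {{CANCER}} Breast, great-aunt, dx at age of 52 {{AUNT}} {{}}
#>   entities: 3 active / 5 total; relations: 2

subset(ann$entities, status == "ACTIVE",
       select = c(surface, label, norm))
#>      surface        label       norm
#>       Breast       BREAST     BREAST
#>   great-aunt FAMILYMEMBER GREAT_AUNT
#> dx at age of 52   ONSET_AGE dx at age of 52

ann$assertions[, c("relative_code", "degree", "condition", "onset_lower")]
#>   relative_code degree condition onset_lower
#> 1    GREAT_AUNT      3    BREAST          52
```

The comment corrected the coded `AUNT` to a great-aunt (third degree) and
supplied the site and onset; the structured `AUNT` stays in the table as an
IGNORED entity and is linked to nothing. Screening this patient finds no
criterion (breast cancer at 52 in a third-degree relative), in either mode —
but change the comment to `"breast ca, dx in 30s"` and the NLP-augmented
mode becomes eligible via BO1 (first/second-degree breast cancer at ≤ 45,
optimistic range policy) while the structured-only mode still sees an
unspecified cancer:

```r
profile <- patient_profiles(fhh_entry("P2", "E2", "CANCER", "AUNT", NA,
                                      "breast ca, dx in 30s"))[[1]]
screen_patient(profile, "NLP_AUGMENTED")[, c("cohort", "eligible")]
#>   cohort         eligible
#> 1 BREAST_OVARIAN TRUE
#> 2 COLORECTAL     FALSE
```

A command-line wrapper with `extract`, `screen`, `simulate` and `evaluate`
subcommands is installed at `inst/cli/fhhscreen.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/fhhscreen.R", package="fhhscreen"))')" \
  simulate --n-patients 100 --seed 7 --out corpus
```

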