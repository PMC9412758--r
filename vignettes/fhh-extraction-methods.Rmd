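---
title: "Extracting family health history from structured fields and comments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extracting family health history from structured fields and comments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fhhscreen)
```

## The data model

The dedicated family-health-history (FHH) section of an EHR stores one
assertion per row: a coded condition, a coded relative, an integer age of
onset, and a short free-text comment. The comment is not independent prose —
it supplements or corrects the structured fields of *that* row. The pipeline
therefore concatenates the four fields into a single string, in the column
order condition, comment, relative, onset, wrapping each structured value in
double curly brackets so that later rules can tell code from narrative. A
missing structured value renders as an empty marker:

```{r}
entry <- fhh_entry("P1", "E1", "CANCER", "AUNT", NA,
                   "Breast, great-aunt, dx at age of 52")
combine_fields(entry)
```

Offsets are 0-based and half-open throughout, which makes slicing
unambiguous and maps directly onto Brat standoff annotations
(`read_brat_standoff()` / `write_brat_standoff()`). Stripping the markers
and the structured values recovers the comment verbatim, and distinct field
tuples always yield distinct marked strings.

Sentence segmentation splits on `". "`, `";"` and newlines only, never
inside a marker and never after the clinical abbreviations `dx.`, `ca.`,
`yr.` and the like. FHH comments are telegraphic; a more aggressive splitter
would separate relatives from their conditions.

## Extraction

Entity extraction is exact lexicon matching: case-insensitive,
hyphen/space-tolerant, longest match wins with leftmost tie-break, and no
two active entities of the same label may overlap. The lexicon ships with
the package (`default_lexicon()`) and is deliberately editable
(`write_lexicon()`/`read_lexicon()`): EHR code lists vary by site, and the
shipped enumerations of condition codes and relative codes are a
reconstruction, not an authoritative vocabulary. It covers:

* cancer sites with synonyms (`gastric` → STOMACH, `renal` → KIDNEY, ...),
  each also matching with an optional `cancer`/`ca` suffix; a generic
  `cancer`/`ca` term; ENDOMETRIAL/UTERINE is included as a site because the
  colorectal criteria need it, even though it sits outside the core subtype
  list;
* cancer syndromes (Lynch, HNPCC, Cowden, Li-Fraumeni, FAP, APC, serrated
  polyposis, polyposis) and pathogenic genes (BRCA1/2, CHEK2, ATM, PALB2,
  TP53, PTEN, CDH1, MLH1, MSH2, PMS2, MSH6, EPCAM, MYH, MUTYH);
* relatives with code, degree of relationship, sex and — where the term
  itself carries it — side of the family (`maternal grandmother`), plus
  nonspecific side-only phrases (`father's side`);
* onset phrase patterns for the four onset subtypes: exact ages (`dx at age
  of 52`), decade ranges (`in his 30s`), calendar periods (`in 1985`),
  non-numeric strings (`10 years ago`), and deceased-age phrases
  (`deceased at age 60 years`).

Decade semantics are conservative sub-decade halves: `early Ns` is
\[N, N+4\], `late Ns` is \[N+5, N+9\], bare `Ns` is \[N, N+9\]. Calendar
periods never yield an age because the entries carry no birth year.

Context rules then (a) flag mentions inside `{{ }}` as `is_structural`,
(b) ignore family members in exclusion contexts such as *lives with her
daughter* and onset numbers describing the patient (*died when pt was 5*),
and (c) set an uncertainty feature on condition entities whose sentence
segment contains a cue (*possible, probably, maybe, "?", unsure, unknown
type, suspected*). The scope of a cue is its segment: the comments are short
enough that finer scoping has nothing to attach to. There is no fuzzy
matching: data-entry typos (*bladdler*) are an accepted error mode, emulated
and measured by the simulator rather than patched over.

## Reconciliation

Conflicts between structural and comment-derived mentions are resolved by a
fixed, ordered rule set. Losing entities are set to IGNORED, never deleted,
so the full annotation remains inspectable. Conditions and onsets are fixed
before relatives:

0. A comment site refines a generic structured CANCER, corrects a different
   structured site, or — when it repeats the structured site — is folded
   into it (passing along any uncertainty hedge). This merge rule keeps a
   repeated mention from double-counting as two cancers.
1. A colorectal-cancer syndrome in the comment overrides a structured colon
   cancer.
2. A comment onset *range* overrides a structured onset age.
3. / 4. A comment onset period or string loses to a structured age. A
   comment *exact age* is treated as a correction of a differing structured
   age (the ordered rules say nothing about this pair; correction is
   consistent with how comment relatives are handled).
5. A deceased age with no structured onset infers an onset range from 0 to
   the deceased age — onset was strictly before death. Whether such an
   inferred range may satisfy an age threshold is configurable
   (`inferred_range_participates`, default on, consistent with the
   optimistic screening posture below).
6. A specific comment relative replaces the structured one, unless a
   conjunction (`and`, `also`, `&`, `+`) immediately precedes it, in which
   case both stay active. "Specific" means any lexicon relative term.
7. A nonspecific side-only phrase keeps the structured relative and sets its
   side feature.
8. A relative with multiplicity N (`2× sisters`, `three aunts`) expands to N
   instances.

Reconciliation is idempotent and never creates condition entities (only
statuses, features, inferred onsets, and multiplicity expansions). Separate
from the ordered rules, comment override terms (*precancer, benign, cyst, no
cancer*) cancel the coded condition entirely; override terms inside markers
never fire.

## Linking and counting

Within each sentence segment, every ACTIVE family-member instance links to
every ACTIVE condition in scope and to the onset in scope. The scope of a
condition is the comment relatives of its own segment plus the structured
relative — comments routinely rely on the structured relative — falling back
to any active relative of the entry; a condition with no relative at all is
reported as an orphan, not an error. When several onsets survive in a
multi-sentence comment, each relative takes the onset of its own segment,
and an assertion pairs a condition with the onset sharing its segment;
this nearest-scope choice is recorded in provenance rather than guessed
globally.

One relative with two cancers yields two condition relations; one cancer
listed for two relatives yields two as well; `2× sisters` yields two
family-member instances and hence two relations. Criteria that count
affected relatives count *relations* (multiplicity-weighted assertion
counts), not distinct persons.

## The criteria engine

Both screening modes feed the same engine. `STRUCTURED_ONLY` builds
assertions from the coded fields alone; `NLP_AUGMENTED` converts the
pipeline output into the same normalized form. Entries not relevant to
familial cancer risk (coded diabetes with no cancer-bearing comment, ...)
are filtered out first in both modes.

Breast/ovarian criteria: BO1 first/second-degree breast cancer at ≤ 45;
BO2 first/second-degree ovarian cancer; BO3 first-degree pancreatic cancer;
BO4 male breast cancer in any relative (the guideline says "a male
relative" without a degree limit, so none is imposed); BO5 three or more
relation-counted first/second-degree relatives with breast or prostate
cancer on one side of the family; BO6 Ashkenazi Jewish ancestry and any
breast or prostate cancer in any relative; BO7 BRCA1/2, CHEK2, ATM, PALB2,
TP53, PTEN or CDH1, or Cowden/Li-Fraumeni syndrome, in any relative.
Colorectal criteria: C1 Lynch/FAP/APC/serrated polyposis/polyposis or MLH1,
MSH2, PMS2, MSH6, EPCAM, MYH, MUTYH in any relative; C2 first-degree colon
cancer at ≤ 50; C3 first-degree endometrial cancer at ≤ 50; C4 three or
more relation-counted first/second-degree relatives on one side with
Lynch/HNPCC or a cancer of the colon, endometrium, ovary, stomach, small
bowel, kidney, ureter, bladder, urethra, brain or pancreas.

Policy choices that were genuinely open, all exposed in `fhh_config()`:

* **Range-threshold policy.** An onset range meets a threshold T when its
  *lower* bound is ≤ T (`OPTIMISTIC`, default): a sister with breast cancer
  "dx in her 30s" should screen in against a 45-year threshold. `STRICT`
  (upper bound ≤ T) is available for high-precision outreach.
* **Uncertainty policy.** `INCLUDE` keeps hedged assertions (maximizing the
  reach of screening), `EXCLUDE` drops them first (minimizing manual
  review). Uncertainty is always carried on the assertion — and exported as
  a boolean extension in the FHIR-style records — so both policies stay
  computable downstream.
* **Colon definition.** Rectal cancer counts as colon cancer for C2/C4 by
  default (colorectal guideline scope); a colon-only definition is a switch.
* **Side counting.** Unknown-side assertions count toward neither side
  (conservative, default); full siblings and the patient's descendants count
  toward both. A switch lets unknown sides count toward both.
* **Degree-3 relatives** (great-aunt, cousin) satisfy only the "any
  relative" criteria (BO4, BO6, BO7, C1); the others are explicitly
  first/second degree.
* **Comment-derived polyposis** qualifies for C1 by default (the guideline
  anchors polyposis to the coded history; a flag restricts C1's syndrome arm
  to coded sources).
* BO6 never fires when the Ashkenazi flag is missing rather than false.

The engine is monotone in evidence — adding an assertion never removes a
matched criterion — which yields two testable nesting properties: the
include-uncertainty eligible set contains the exclude-uncertainty set, and
on corpora whose comments only supplement (never contradict) the structured
fields, the NLP-augmented eligible set contains the structured-only set.

## The synthetic corpus

No study corpus is distributable, so `generate_corpus()` produces one with
gold annotations computed constructively: the generator knows which
relative, condition and onset each template intends, and gold eligibility is
the criteria engine applied to those intended assertions. Templates are
authored from the comment phenomena the real section exhibits —
supplementary sites and onsets, relative corrections, conjunctions,
side-only phrases, multiplicities, uncertainty hedges, condition overrides,
syndrome overrides, deceased ages, gene mentions, irrelevant non-cancer
entries, and exclusion contexts — with default proportions chosen so that
plain structured-only rows dominate (25%) and each correction phenomenon
stays a minority (2–12%), echoing a section where most rows need no
narrative.

Each entry draws its phenomenon independently, so observed frequencies are
multinomial around the requested proportions (tested at 3σ). Designated
eligible proportions (defaults 15% breast/ovarian, 10% colorectal — a
primary-care population enriched for family history worth screening) are
*floors*: one injected, flagged entry guarantees the criterion; free entries
can add eligible patients by chance. Typo perturbation duplicates a letter
inside a comment condition term at a seeded rate and leaves gold unchanged:
a typo is meant to be missed, so recall can only fall.

What passing the end-to-end suite shows — and what it does not: on a clean
2,000-entry corpus the pipeline recovers the gold relations with F1 = 1.0
and reproduces gold eligibility exactly, which validates the internal
consistency of extraction, reconciliation, linking and the engine under
every templated phenomenon. It does not measure performance on real
clinical text, whose vocabulary, typos and ambiguities (e.g. a coded colon
cancer with the bare comment "ileum") exceed any template inventory; the
published experience with a real corpus is mid-0.9 relation F1, not 1.0.

## Evaluation choices

A predicted relation is a true positive only when the relation type, both
linked entity identities and the feature values (side, uncertainty, onset
kind and bounds) match the gold relation of the same entry; metrics are
micro-averaged from confusion counts summed over relation types. Bootstrap
intervals are percentile intervals (the simplest faithful choice where no
variant is specified), B = 1,000 by default, resampling FHH entries for
relation metrics and patients for eligibility metrics; the resampling unit
is recorded with the output. Intervals for relation types carried by fewer
than two entries — or whose metric is undefined in most resamples — are
flagged unavailable rather than reported as zero-width. Reported tables
round half-up to two decimals.

Degenerate inputs are policy, not accidents: zero-denominator metrics are
undefined (`NA`), never 0; an onset of kind PERIOD or STRING never meets an
age threshold; multiplicity 0 is treated as 1 with a warning; a condition
with no relative is an orphan warning.

## Problem sizes

The shipped tests run the full pipeline over corpora of roughly 60–150
patients per property, plus one 850-patient (~2,300-entry) end-to-end
recovery suite; at the measured ~15 ms per entry the whole suite completes
in a few minutes on one CPU. These sizes give the binomial frequency checks
and nesting properties comfortable power while staying far from any
meaningful runtime.

## Known limitations

* Exact lexicon matching: misspellings and out-of-vocabulary phrasings are
  missed by design; the lexicon is the extension point.
* No coreference across entries or patients, and no merging of the same
  relative mentioned in two entries — counts are per relation, as the
  counting criteria require.
* Aggregated cancer categories (gynecologic, gastrointestinal,
  genitourinary) are representable in the schema but excluded from
  extraction output; they inflate false positives against site-specific
  criteria.
* PERIOD onsets are kept as text; converting *in 1985* to an age would
  require a birth year the section does not store.
* The criteria cover family-history-based testing of unaffected patients
  only; personal cancer history is out of scope.
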