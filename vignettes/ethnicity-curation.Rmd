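---
title: "Curating ethnicity codes across linked health-record sources"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curating ethnicity codes across linked health-record sources}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(ethnocurate)
```

## The problem

Self-reported ethnicity enters English health records through two coding
systems of very different resolution. Primary-care (GDPPR-like) records carry
fine-grained clinical-terminology concepts — hundreds of distinct codes such
as "Punjabi speaking Indian" or "Greek Cypriot" — alongside the 19
census-aligned NHS letter categories (A–Z). Hospital admission (HES-like)
records carry letters only, based on the older 2001 census classification,
and may still contain pre-2001 numeric codes. Most research collapses
everything to six high-level groups (White; Mixed; Asian/Asian British;
Black/African/Caribbean/Black British; Other Ethnic Groups; Unknown).

A person accumulates many ethnicity records over decades of contacts, across
both sources, and these records conflict surprisingly often. `ethnocurate`
implements the curation pipeline end to end: a three-level classification
hierarchy, a source-prioritisation decision tree that resolves one ethnicity
per person, and an audit of completeness, consistency and granularity. A
synthetic cohort generator reproduces the statistical structure of the real
data, which sit in a secure environment and cannot be shipped.

## The classification hierarchy

The `codebook` object holds three levels and the maps between them:

1. **Concepts** — opaque terminology codes, each mapped to exactly one NHS
   letter. Concepts never map to the "not known" categories `X`/`99`.
2. **NHS letters** — 19 categories. `Z` ("not stated": the person was asked
   and declined or could not answer) is one of the 19 but is treated as
   *non-informative*, as are `X` and `99` ("not known": the person was never
   asked), which sit outside the 19.
3. **High-level groups** — the six-way aggregation, under three *dialects*:
   `SDE` (the convention used inside the secure data environment, which
   follows the 2001 census in placing Chinese `R` and Gypsy/Irish Traveller
   `T` under Other Ethnic Groups) and `CENSUS_2011`/`CENSUS_2021` (which
   place `R` under Asian/Asian British and `T` under White). The dialects
   disagree on exactly `{R, T}`:

```{r}
cb <- load_codebook(system.file("extdata", "codebook_synthetic.csv",
                                package = "ethnocurate"))
list_dialect_discrepancies(cb, "SDE", "CENSUS_2011")
```

Legacy numerals 1–9 translate to single letters; `0` meant "White" without
distinguishing British/Irish/other, so it translates to a
`WHITE_UNSPECIFIED` sentinel rather than arbitrarily picking one of A/B/C —
the sentinel still aggregates to high-level White, which is all the numeral
ever asserted. The letters I, O, Q, U, V and Y are not part of the scheme
and are rejected by the loader rather than passed through.

The shipped codebook is a **synthetic stand-in**: the true concept-to-letter
mapping table is access-restricted, and no mapping algorithm for it has been
published, so the fixture encodes one defensible assignment per concept.
Descriptor classification (does a label mention an ethnicity/race term, a
religion, a geography, a language?) is keyword-driven through
`classify_concept_descriptors()`; the shipped keyword lists are a
configurable convention, not a canonical standard, because the rules behind
the published descriptor counts are not documented.

## The decision tree

`resolve_person()` / `harmonise_cohort()` consult sources in fixed priority
order, and a later stage is consulted only when every earlier stage holds no
informative code:

1. concept-coded primary-care records;
2. letter-coded primary-care records;
3. hospital records (letters; legacy numerals are translated);
4. otherwise Unknown with provenance `NONE`.

Within the winning stage one record is selected. `MOST_RECENT` (the default,
matching the study convention of using the most recent record, which keeps
newly introduced concepts visible) takes the latest informative record;
`MOST_FREQUENT` takes the modal letter, which is more robust to one-off data
entry errors. Choices the published account leaves open are fixed
deterministically and documented here:

* **Date ties** under `MOST_RECENT` prefer concept-coded over letter-coded
  records, then the lexicographically smallest code. Frequency ties under
  `MOST_FREQUENT` go to the most recently recorded letter.
* **Missing dates** rank below all dated records instead of being dropped —
  the record can still resolve a person who has nothing else.
* **`Z` never blocks fallback** by default: a "not stated" in primary care
  does not stop an informative hospital letter from being used, because the
  published completeness flow pools "not stated" with "no record" and
  prefers any informative source. Whether the original study consulted
  hospital data for Z-only persons is not explicit, so the opposite
  behaviour is available via `z_blocks_fallback = TRUE`
  (`--no-z-fallback` on the command line).
* **Unknown codes** (absent from the codebook) are logged and treated as
  non-informative rather than fatal, so one bad row cannot poison a cohort
  run.

Eligibility is applied before any resolution: persons with age below 0 or
115 and over, or missing sex, are excluded and logged.

```{r}
resolve_person(
  gdppr_records = tibble::tibble(person_id = "p", coding_system = "SNOMED",
                                 code = "100000081",
                                 record_date = as.Date("2015-06-01")),
  hes_records = tibble::tibble(person_id = "p", code = "N",
                               record_date = as.Date("2021-01-01")),
  cb = cb)
```

## The audit

* **Completeness** is reported under both missingness definitions: *strict*
  (no record in either source) and *pooled* (no record, or only
  non-informative codes), alongside per-provenance counts.
* **Multiplicity** is the fraction of persons with at least two distinct
  letter-level codes in a stream, among persons with at least one code in
  that stream. Concept records are converted to letters first, because the
  comparison is defined over the 19 categories, not over raw concepts.
  Dropping `Z` from the per-person code sets (`include_z = FALSE`) can only
  lower these rates; denominators are unchanged.
* **Pair tables** add one count per unordered pair of distinct letters per
  person, so a person with three distinct codes contributes all three
  pairings and the table mass equals the sum over persons of
  $\binom{k_p}{2}$.
* **Granularity** counts used versus defined concepts. Whether "used" means
  *ever recorded* or *selected as someone's resolved record* is ambiguous in
  the published account, so both are provided
  (`used_definition = "any"` / `"resolved"`); `"any"` is the default as the
  more inclusive reading.
* **Descriptor diversity** tallies the flags over used concepts; flags
  overlap, so the fractions need not sum to one.
* **The discrepancy audit** lists exactly the persons whose resolved letter
  lies in the dialect-difference set — the individuals whose published
  high-level group depends on the aggregation convention.
* Percentages are printed to one decimal using round-half-away-from-zero,
  with raw counts always emitted alongside. Small-cell suppression is
  available (`small_cell_threshold`) but off by default; disclosure rules of
  any particular secure environment are out of scope.

## What the synthetic generator emulates

`synthetic_config()` defaults *are* the study conditions:

* a six-group mixture set to the recorded-population distribution (White
  77.3%, Asian/Asian British 9.8%, Black/African/Caribbean/Black British
  3.6%, Other Ethnic Groups 3.6%, Mixed 2.2%, Unknown 3.2%, renormalised);
* `p_missing_gdppr = 0.167` (one person in six has no primary-care
  ethnicity record) and `p_hes_rescue = 0.635`, so overall strict
  missingness lands near 6%, matching the reduction seen when hospital
  records are linked;
* a concept codebook of 489 codes of which an expected 255 are "in
  circulation" — records draw only from the circulating subset, so roughly
  half the vocabulary is never assigned to anyone;
* per-person record counts drawn geometric with mean 2 — the real
  per-person distribution is unpublished, so this is a modelling choice,
  flagged as such;
* conflicting extra codes injected at `conflict_rate = 0.12` (a modelling
  choice placing concept-stream multiplicity in the mid-teens, the reported
  neighbourhood), drawn preferentially from the code pairs most often seen
  co-occurring nationally (A–C, A–Z, C–S; among minority codes L–S, N–P,
  H–L), so audit outputs are qualitatively comparable to the real ones;
* "not stated" replacement of any record at `p_not_stated = 0.05`;
* hospital records never carry `T` or `W` (absent from the 2001-based
  hospital scheme); those letters are substituted by `S`, which preserves
  the high-level group under the SDE dialect. Hospital records carry a
  legacy numeral at a low configurable rate, exercising the translation
  path.

Missingness is *informative*: the probability of having no primary-care
record is logistic in sex and the 18–29 age band (males and young adults
more often missing, the pattern observed in the real register), with the
intercept solved numerically so the marginal rate equals `p_missing_gdppr`
exactly. This calibration is what makes the parameter-recovery checks sharp:
the audited strict-missing fraction must land within three binomial standard
deviations of `p_missing_gdppr * (1 - p_hes_rescue)`.

Determinism: one integer seed; the codebook, population and record tables
use fixed seed offsets (+1, +2, +3), so any table can be regenerated
independently and full runs are byte-identical.

What the generator does **not** emulate: realistic visit-level content,
geography below region, correlation between ethnicity and
age/region/deprivation, coding-practice drift over calendar time, and the
true concept mapping. Passing tests therefore demonstrate that the
*pipeline* is correct and calibrated under the stated structure, not that
the synthetic cohort reproduces every marginal of the real register.

## Verification strategy and problem sizes

The test suite pins the decision tree to an independent brute-force oracle
by exhaustive enumeration of record configurations (up to four records drawn
from a six-code pool spanning all three streams and two dates), pins pair
counting to per-person enumeration over 200 random cohorts, and checks
recovery of generator parameters on a cohort of 100,000 persons — large
enough that three binomial standard deviations of the strict-missing
fraction is a band of about ±0.23 percentage points. Recovery checks run in
the conflict-free regime (`conflict_rate = 0`, `p_not_stated = 0`), where
the mixture is identified and resolution must reproduce the latent group
*exactly* for every person with a record; conflict injection is tested
separately through the monotonicity and multiplicity properties. Worked
arithmetic from the published summary tables (column totals, row
percentages, the 255-of-489 used-concept fraction) is asserted at printed
precision.

## Known limitations

* The shipped codebook is synthetic; results on it characterise the
  pipeline, not the restricted national mapping.
* Cross-source identity linkage is out of scope: persons arrive pre-linked
  by `person_id`.
* Conflicting codes that cannot be reconciled (e.g. White vs Black in one
  record) are resolved by recency or frequency, not adjudicated; the
  `had_conflict` flag and the pair tables exist precisely so downstream
  users can quantify how much of a cohort is affected.
* The descriptor keyword lists are heuristics; counts derived from them are
  convention-dependent.
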