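# ethnocurate

Curation and quality audit of self-reported ethnicity in linked English
health records.

## The problem

Ethnicity reaches health records through classifications of very different
resolution. Primary-care (GDPPR-like) records code it either as fine-grained
clinical-terminology concepts (hundreds of codes such as "Punjabi speaking
Indian") or as one of the 19 census-aligned NHS letter categories (A–Z);
hospital admission (HES-like) records use letters only, on the older
2001-census scheme, sometimes still as pre-2001 numerals 0–9. Research
usually collapses all of this to six high-level groups — White; Mixed;
Asian/Asian British; Black/African/Caribbean/Black British; Other Ethnic
Groups; Unknown — and two aggregation conventions are in circulation that
disagree on exactly two letters: Chinese (`R`) and Gypsy/Irish Traveller
(`T`) sit under Other Ethnic Groups in the secure-data-environment
convention but under Asian and White respectively in the 2011/2021 census
conventions.

People accumulate many ethnicity records across both sources, and the
records conflict often. `ethnocurate` gives analysts of such data:

* a validated three-level **codebook** (concept → NHS letter → high-level
  group under the `SDE`, `CENSUS_2011` and `CENSUS_2021` dialects), with
  legacy-numeral translation (`0` maps to a `WHITE_UNSPECIFIED` sentinel —
  the numeral never said which White letter was meant);
* a **source-prioritisation decision tree** resolving one ethnicity per
  person: concept-coded primary-care records, then letter-coded primary-care
  records, then hospital records, each stage consulted only when every
  earlier one holds no informative code (`Z`, `X`, `99` are non-informative
  and never block the fallback by default); within a stage, selection is
  `MOST_RECENT` (default) or `MOST_FREQUENT`, with deterministic tie rules;
* a **synthetic cohort generator** reproducing the statistical structure of
  the real, access-restricted data (six-group mixture, record multiplicity
  with conflicting codes, "not stated" codes, informative missingness
  calibrated to an exact marginal rate);
* an **audit** of completeness (strict and pooled missingness), multiplicity
  of differing codes per person, co-occurring code-pair tables, concept
  granularity (used vs defined), descriptor diversity of concept labels, a
  dialect-discrepancy audit, and stratified cohort characteristics.

## Worked example

Generate a 10,000-person synthetic cohort under the default study
conditions, resolve one ethnicity per person, and audit it:

```r
library(ethnocurate)

cfg      <- synthetic_config(n_persons = 10000, seed = 1)
cb       <- generate_codebook(cfg)
persons  <- generate_population(cfg)
recs     <- generate_records(persons, cb, cfg)
resolved <- harmonise_cohort(persons, recs$gdppr, recs$hes, cb,
                             dialect = "SDE", strategy = "MOST_RECENT")
audit_report(persons, resolved, recs$gdppr, recs$hes, cb)
#> <audit_report>
#>   cohort size:          9950
#>   complete (GDPPR):     7810 (78.5%)
#>   complete (post-link): 8944 (89.9%)
#>   missing (strict):     608 (6.1%)
#>   missing (pooled):     1006 (10.1%)
#>   concepts used:        259 / 489 (53.0%)
```

Reading the output: 9,950 of the 10,000 simulated persons pass the
eligibility filter (valid age, known sex); 78.5% resolve from primary care
and the hospital fallback lifts informative completeness to 89.9%; 6.1% have
no ethnicity record in either source (the *strict* definition) while 10.1%
are missing once persons with only "not stated"/"not known" codes are pooled
in; and 259 of the 489 concept codes in the generated vocabulary were ever
assigned to anyone — roughly half the vocabulary goes unused, as in the real
register.

The most frequently co-occurring code pairs in the primary-care stream show
the expected pattern — the White letters and "not stated" dominate:

```r
head(audit_report(persons, resolved, recs$gdppr, recs$hes, cb)$pair_table_gdppr, 5)
#>   letter_a letter_b count
#> 1 A        Z          657
#> 2 A        C          457
#> 3 C        Z          101
#> 4 C        S           53
#> 5 H        L           45
```

Single persons can be resolved directly; here a concept-coded primary-care
record beats a newer hospital letter, and the conflict is flagged:

```r
resolve_person(
  gdppr_records = tibble::tibble(person_id = "p", coding_system = "SNOMED",
                                 code = "100000081",
                                 record_date = as.Date("2015-06-01")),
  hes_records   = tibble::tibble(person_id = "p", code = "N",
                                 record_date = as.Date("2021-01-01")),
  cb = load_codebook(system.file("extdata", "codebook_synthetic.csv",
                                 package = "ethnocurate")))
#>   person_id concept_code nhs_letter          high_level   provenance
#> 1         p    100000081          H Asian/Asian British GDPPR_SNOMED
#>   had_conflict n_distinct_informative_codes had_any_record
#> 1         TRUE                            2           TRUE
```

The same pipeline runs from the shell against CSV inputs
(`inst/scripts/ethnocurate` is a thin wrapper over `run_cli()`):

```sh
Rscript inst/scripts/ethnocurate generate  --out-dir run --seed 1
Rscript inst/scripts/ethnocurate harmonise --out-dir run --dialect sde
Rscript inst/scripts/ethnocurate audit     --out-dir run
Rscript inst/scripts/ethnocurate demo
```

`harmonise` writes `resolved.csv` plus an eligibility exclusion log and a
`run_meta.yaml` sidecar; `audit` writes `audit_report.json`,
`audit_report.md` and the pair tables. Useful switches:
`--strategy most-frequent`, `--no-hes-fallback`, `--no-z-fallback`,
`--used-definition resolved`, `--skip-descriptors`, and a YAML run
configuration via `--config`.

## Learning more

The methods vignette (`vignettes/ethnicity-curation.Rmd`) documents the
hierarchy, the decision tree and its tie rules, what the synthetic generator
does and does not emulate, the calibration of informative missingness, and
the package's design decisions on points the published record leaves open.
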