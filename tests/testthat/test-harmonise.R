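test_that("eligibility filter applies the age and sex rules at the boundaries", {
  persons <- tibble::tibble(
    person_id = c("a", "b", "c", "d", "e", "f"),
    age = c(115L, 114L, 0L, -1L, 40L, 40L),
    sex = c("F", "F", "M", "M", NA, "F"))
  out <- apply_eligibility_filter(persons)
  expect_setequal(out$eligible$person_id, c("b", "c", "f"))
  expect_identical(
    out$exclusions$reason[out$exclusions$person_id == "a"], "invalid_age")
  expect_identical(
    out$exclusions$reason[out$exclusions$person_id == "e"], "missing_sex")
})

test_that("within-source selection follows the stated tie rules", {
  cb <- fixture_codebook()
  two <- ethnocurate:::annotate_letters(
    gdppr_rec("p", "NHS", c("H", "L"), c("2019-01-01", "2021-06-30")), cb)
  expect_identical(select_within_source(two, "MOST_RECENT")$letter, "L")

  mode3 <- ethnocurate:::annotate_letters(
    gdppr_rec("p", "NHS", c("H", "H", "L"),
              c("2018-01-01", "2019-01-01", "2021-01-01")), cb)
  expect_identical(select_within_source(mode3, "MOST_FREQUENT")$letter, "H")

  only_z <- ethnocurate:::annotate_letters(
    gdppr_rec("p", "NHS", "Z", "2020-01-01"), cb)
  expect_null(select_within_source(only_z, "MOST_RECENT"))
  expect_null(select_within_source(only_z, "MOST_FREQUENT"))

  # date tie resolves to the lexicographically smallest code
  tie <- ethnocurate:::annotate_letters(
    gdppr_rec("p", "SNOMED", c("100000151", "100000141"),
              c("2020-08-08", "2020-08-08")), cb)
  expect_identical(select_within_source(tie, "MOST_RECENT")$code,
                   "100000141")

  # records with missing dates rank below all dated records
  undated <- ethnocurate:::annotate_letters(
    gdppr_rec("p", "NHS", c("H", "L"), c(NA, "1999-01-01")), cb)
  expect_identical(select_within_source(undated, "MOST_RECENT")$letter, "L")

  # frequency ties go to the most recently recorded letter
  freq_tie <- ethnocurate:::annotate_letters(
    gdppr_rec("p", "NHS", c("H", "H", "L", "L"),
              c("2010-01-01", "2011-01-01", "2012-01-01", "2020-01-01")), cb)
  expect_identical(select_within_source(freq_tie, "MOST_FREQUENT")$letter,
                   "L")
})

test_that("the decision tree prioritises sources in the documented order", {
  cb <- fixture_codebook()
  # concept-coded primary care beats hospital
  r1 <- resolve_person(gdppr_rec("p", "SNOMED", "100000081", "2015-01-01"),
                       hes_rec("p", "N", "2021-01-01"), cb)
  expect_identical(r1$provenance, "GDPPR_SNOMED")
  expect_identical(r1$high_level, "Asian/Asian British")
  expect_identical(r1$nhs_letter, "H")

  # hospital legacy numeral is translated on fallback
  r2 <- resolve_person(empty_gdppr(), hes_rec("p", "4", "2018-07-15"), cb)
  expect_identical(r2$nhs_letter, "H")
  expect_identical(r2$provenance, "HES")

  # not-stated everywhere resolves to Unknown/NONE
  r3 <- resolve_person(gdppr_rec("p", "NHS", "Z", "2019-01-01"),
                       hes_rec("p", "Z", "2020-01-01"), cb)
  expect_identical(r3$provenance, "NONE")
  expect_identical(r3$high_level, "Unknown")
  expect_true(r3$had_any_record)

  r4 <- resolve_person(empty_gdppr(), empty_hes(), cb)
  expect_identical(r4$provenance, "NONE")
  expect_false(r4$had_any_record)

  # letter-coded primary care beats hospital even when older
  r5 <- resolve_person(gdppr_rec("p", "NHS", "A", "2001-01-01"),
                       hes_rec("p", "N", "2021-01-01"), cb)
  expect_identical(r5$provenance, "GDPPR_NHS")
  expect_identical(r5$nhs_letter, "A")
})

test_that("the demo cohort resolves to the hand-derived table", {
  cb <- load_codebook(demo_path("codebook.csv"))
  persons <- read_persons(demo_path("persons.csv"))
  gdppr <- read_gdppr_records(demo_path("gdppr_records.csv"))
  hes <- read_hes_records(demo_path("hes_records.csv"))
  res <- harmonise_cohort(persons, gdppr, hes, cb)

  expected <- tibble::tribble(
    ~person_id, ~concept_code, ~nhs_letter, ~high_level, ~provenance,
    ~had_conflict, ~n_distinct_informative_codes, ~had_any_record,
    "P01", "100000081", "H", "Asian/Asian British", "GDPPR_SNOMED",
    FALSE, 1L, TRUE,
    "P02", NA, "A", "White", "GDPPR_NHS", FALSE, 1L, TRUE,
    "P03", NA, "H", "Asian/Asian British", "HES", FALSE, 1L, TRUE,
    "P04", NA, NA, "Unknown", "NONE", FALSE, 0L, TRUE,
    "P05", NA, NA, "Unknown", "NONE", FALSE, 0L, FALSE,
    "P06", "100000021", "C", "White", "GDPPR_SNOMED", TRUE, 2L, TRUE,
    "P07", "100000121", "R", "Other Ethnic Groups", "GDPPR_SNOMED",
    FALSE, 1L, TRUE,
    "P08", NA, "M", "Black/African/Caribbean/Black British", "HES",
    FALSE, 1L, TRUE,
    "P11", NA, "N", "Black/African/Caribbean/Black British", "HES",
    FALSE, 1L, TRUE,
    "P12", "100000141", "N", "Black/African/Caribbean/Black British",
    "GDPPR_SNOMED", TRUE, 2L, TRUE)
  got <- res[order(res$person_id), ]
  attributes(got) <- attributes(got)[c("names", "class", "row.names")]
  expect_equal(as.data.frame(got), as.data.frame(expected),
               ignore_attr = TRUE)
  expect_setequal(attr(res, "exclusions")$person_id, c("P09", "P10"))
})

test_that("degenerate cohorts and duplicate persons are handled", {
  cb <- fixture_codebook()
  persons <- persons_row(c("a", "b"))
  res <- harmonise_cohort(persons, empty_gdppr(), empty_hes(), cb)
  expect_identical(nrow(res), 2L)
  expect_true(all(res$provenance == "NONE"))

  expect_error(
    harmonise_cohort(persons_row(c("a", "a")), empty_gdppr(), empty_hes(),
                     cb),
    "duplicate")
})

test_that("the Z code never blocks fallback unless asked to", {
  cb <- fixture_codebook()
  g <- gdppr_rec("p", "NHS", "Z", "2021-01-01")
  h <- hes_rec("p", "N", "2015-04-04")
  default <- resolve_person(g, h, cb)
  expect_identical(default$provenance, "HES")
  expect_identical(default$nhs_letter, "N")
  blocked <- resolve_person(g, h, cb, z_blocks_fallback = TRUE)
  expect_identical(blocked$provenance, "NONE")
  expect_identical(blocked$high_level, "Unknown")
})

test_that("unknown codes are logged and treated as non-informative", {
  cb <- fixture_codebook()
  persons <- persons_row("p")
  g <- gdppr_rec("p", c("SNOMED", "NHS"), c("999999999", "H"),
                 c("2022-01-01", "2001-01-01"))
  res <- harmonise_cohort(persons, g, empty_hes(), cb)
  expect_identical(res$nhs_letter, "H")
  expect_identical(res$provenance, "GDPPR_NHS")
  expect_identical(attr(res, "unknown_codes"), "999999999")
})

test_that("cohort resolution agrees with per-person resolution", {
  cb <- fixture_codebook()
  for (seed in c(101, 202)) {
    coh <- random_cohort(40, cb, seed)
    for (strategy in c("MOST_RECENT", "MOST_FREQUENT")) {
      res <- harmonise_cohort(coh$persons, coh$gdppr, coh$hes, cb,
                              strategy = strategy)
      for (i in seq_len(nrow(coh$persons))) {
        pid <- coh$persons$person_id[i]
        single <- resolve_person(
          coh$gdppr[coh$gdppr$person_id == pid, ],
          coh$hes[coh$hes$person_id == pid, ], cb, strategy = strategy)
        row <- res[res$person_id == pid, ]
        expect_identical(row$nhs_letter, single$nhs_letter)
        expect_identical(row$provenance, single$provenance)
        expect_identical(row$high_level, single$high_level)
        expect_identical(row$n_distinct_informative_codes,
                         single$n_distinct_informative_codes)
      }
    }
  }
})

test_that("priority, monotone completeness and dialect invariance hold", {
  cb <- fixture_codebook()
  coh <- random_cohort(150, cb, seed = 404)
  res <- harmonise_cohort(coh$persons, coh$gdppr, coh$hes, cb)

  # no person with an informative concept-coded record resolves from HES
  ann <- ethnocurate:::annotate_letters(coh$gdppr, cb)
  has_snomed_inf <- unique(
    ann$person_id[ann$coding_system == "SNOMED" & ann$informative])
  expect_false(any(res$provenance[res$person_id %in% has_snomed_inf] ==
                     "HES"))

  no_hes <- harmonise_cohort(coh$persons, coh$gdppr, coh$hes, cb,
                             hes_fallback = FALSE)
  expect_gte(sum(res$provenance != "NONE"),
             sum(no_hes$provenance != "NONE"))

  alt <- harmonise_cohort(coh$persons, coh$gdppr, coh$hes, cb,
                          dialect = "CENSUS_2011")
  expect_identical(res$nhs_letter, alt$nhs_letter)
  expect_identical(res$concept_code, alt$concept_code)
  changed <- which(res$high_level != alt$high_level)
  disc <- list_dialect_discrepancies(cb, "SDE", "CENSUS_2011")
  expect_true(all(res$nhs_letter[changed] %in% disc))

  # switching strategy only moves persons holding >1 distinct informative code
  freq <- harmonise_cohort(coh$persons, coh$gdppr, coh$hes, cb,
                           strategy = "MOST_FREQUENT")
  differs <- xor(is.na(res$nhs_letter), is.na(freq$nhs_letter)) |
    (!is.na(res$nhs_letter) & !is.na(freq$nhs_letter) &
       res$nhs_letter != freq$nhs_letter)
  moved <- which(differs)
  expect_true(all(res$n_distinct_informative_codes[moved] > 1))
})
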