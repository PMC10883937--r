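make_resolved <- function(provenances, had_any = NULL) {
  n <- length(provenances)
  if (is.null(had_any)) had_any <- provenances != "NONE"
  tibble::tibble(
    person_id = sprintf("q%03d", seq_len(n)),
    concept_code = NA_character_,
    nhs_letter = ifelse(provenances == "NONE", NA_character_, "A"),
    high_level = ifelse(provenances == "NONE", "Unknown", "White"),
    provenance = provenances,
    had_conflict = FALSE,
    n_distinct_informative_codes = as.integer(provenances != "NONE"),
    had_any_record = had_any)
}

test_that("completeness arithmetic matches hand computation", {
  res <- make_resolved(c(rep("GDPPR_SNOMED", 7), rep("HES", 2), "NONE"),
                       had_any = c(rep(TRUE, 9), FALSE))
  comp <- completeness_summary(res)
  expect_identical(comp$n_total, 10L)
  expect_identical(comp$n_complete_post_linkage, 9L)
  expect_identical(comp$pct_complete_post_linkage, 90.0)
  expect_identical(comp$n_complete_gdppr, 7L)
  expect_identical(comp$pct_complete_gdppr, 70.0)
  expect_identical(comp$n_missing_strict, 1L)
  expect_identical(comp$n_missing_pooled, 1L)
  # provenance partition sums to the cohort size
  expect_identical(sum(comp$by_provenance$n), comp$n_total)

  all_none <- completeness_summary(make_resolved(rep("NONE", 5)))
  expect_identical(all_none$pct_complete_post_linkage, 0)
  expect_identical(all_none$n_missing_strict, 5L)

  # strict vs pooled separate "no record" from "not stated"
  mix <- completeness_summary(make_resolved(c("GDPPR_NHS", "NONE", "NONE"),
                                            had_any = c(TRUE, TRUE, FALSE)))
  expect_identical(mix$n_missing_strict, 1L)
  expect_identical(mix$n_not_stated, 1L)
  expect_identical(mix$n_missing_pooled, 2L)
})

test_that("multiplicity counts distinct letters after conversion", {
  cb <- fixture_codebook()
  # one person whose two concepts map to A and C, one single-coded person
  g <- gdppr_rec(c("m1", "m1", "m2"), "SNOMED",
                 c("100000001", "100000021", "100000081"),
                 c("2020-01-01", "2021-01-01", "2020-01-01"))
  rates <- multiplicity_rates(g, empty_hes(), cb, include_z = TRUE)
  snomed <- rates[rates$stream == "gdppr_snomed", ]
  expect_identical(snomed$n_persons, 2L)
  expect_identical(snomed$n_multiple, 1L)
  expect_identical(snomed$pct, 50.0)

  # {A, Z} counts as multiple only when Z is kept
  gz <- gdppr_rec(c("z1", "z1"), "NHS", c("A", "Z"),
                  c("2020-01-01", "2021-01-01"))
  with_z <- multiplicity_rates(gz, empty_hes(), cb, include_z = TRUE)
  without_z <- multiplicity_rates(gz, empty_hes(), cb, include_z = FALSE)
  expect_identical(with_z$n_multiple[with_z$stream == "gdppr_nhs"], 1L)
  expect_identical(without_z$n_multiple[without_z$stream == "gdppr_nhs"], 0L)
  # denominators are unchanged by the Z exclusion
  expect_identical(with_z$n_persons, without_z$n_persons)

  single <- multiplicity_rates(
    gdppr_rec("s1", "NHS", "A", "2020-01-01"),
    hes_rec("s1", "A", "2020-01-01"), cb, include_z = TRUE)
  expect_true(all(single$n_multiple == 0L))
})

test_that("excluding Z never increases a multiplicity rate", {
  cb <- fixture_codebook()
  for (seed in c(7, 77, 777)) {
    coh <- random_cohort(80, cb, seed)
    with_z <- multiplicity_rates(coh$gdppr, coh$hes, cb, include_z = TRUE)
    without_z <- multiplicity_rates(coh$gdppr, coh$hes, cb,
                                    include_z = FALSE)
    expect_true(all(without_z$n_multiple <= with_z$n_multiple))
  }
})

test_that("pair counting enumerates each unordered pair once per person", {
  cb <- fixture_codebook()
  g <- gdppr_rec(rep("p1", 3), "NHS", c("A", "C", "Z"),
                 c("2019-01-01", "2020-01-01", "2021-01-01"))
  pairs <- cooccurrence_pairs(g, cb)
  expect_identical(nrow(pairs), 3L)
  expect_true(all(pairs$count == 1L))
  expect_setequal(paste(pairs$letter_a, pairs$letter_b),
                  c("A C", "A Z", "C Z"))

  expect_identical(nrow(cooccurrence_pairs(
    gdppr_rec("p1", "NHS", "A", "2020-01-01"), cb)), 0L)

  two <- dplyr::bind_rows(
    gdppr_rec(c("p1", "p1"), "NHS", c("A", "C"),
              c("2019-01-01", "2020-01-01")),
    gdppr_rec(c("p2", "p2"), "NHS", c("A", "C"),
              c("2019-01-01", "2020-01-01")))
  t2 <- cooccurrence_pairs(two, cb)
  expect_identical(t2$count, 2L)
  expect_identical(t2$letter_a, "A")

  # duplicate codes do not inflate the pair count
  dup <- gdppr_rec(rep("p1", 3), "NHS", c("A", "A", "C"),
                   c("2019-01-01", "2019-06-01", "2020-01-01"))
  expect_identical(cooccurrence_pairs(dup, cb)$count, 1L)
})

test_that("granularity accounting is exact and exhaustive", {
  cb <- fixture_codebook()
  n_def <- nrow(cb$concepts)

  none <- granularity_summary(empty_gdppr(), cb)
  expect_identical(none$n_used, 0L)
  expect_identical(none$n_unused, n_def)

  all_used <- gdppr_rec(sprintf("g%03d", seq_len(n_def)), "SNOMED",
                        cb$concepts$concept_code, "2020-01-01")
  full <- granularity_summary(all_used, cb)
  expect_identical(full$n_used, n_def)
  expect_identical(full$n_unused, 0L)
  expect_identical(full$pct_used, 100.0)

  # the resolved definition counts only each person's selected concept
  g <- gdppr_rec(c("p1", "p1"), "SNOMED", c("100000081", "100000091"),
                 c("2019-01-01", "2021-01-01"))
  any_def <- granularity_summary(g, cb, used_definition = "any")
  resolved_def <- granularity_summary(g, cb, used_definition = "resolved")
  expect_identical(any_def$n_used, 2L)
  expect_identical(resolved_def$n_used, 1L)
  expect_identical(resolved_def$used_concepts, "100000091")
  expect_true(all(resolved_def$used_concepts %in% any_def$used_concepts))
  expect_identical(any_def$n_used + any_def$n_unused, n_def)
})

test_that("descriptor prevalence equals a direct tally of the flags", {
  cb <- fixture_codebook()
  used <- cb$concepts$concept_code[1:20]
  got <- descriptor_prevalence(cb, used)
  sub <- cb$concepts[cb$concepts$concept_code %in% used, ]
  expect_identical(got$n_flagged[got$flag == "ETHNICITY_RACE"],
                   sum(sub$flag_ethnicity_race))
  expect_identical(got$n_flagged[got$flag == "RELIGION"],
                   sum(sub$flag_religion))
  expect_identical(got$n_flagged[got$flag == "GEOGRAPHY"],
                   sum(sub$flag_geography))
  expect_identical(got$n_flagged[got$flag == "LANGUAGE"],
                   sum(sub$flag_language))
  expect_true(all(got$n_used == 20L))

  expect_warning(empty <- descriptor_prevalence(cb, character()),
                 "undefined")
  expect_true(all(empty$n_flagged == 0L))
})

test_that("the discrepancy audit equals brute-force re-aggregation", {
  cb <- fixture_codebook()
  res <- tibble::tibble(
    person_id = c("p1", "p2", "p3", "p4"),
    concept_code = NA_character_,
    nhs_letter = c("R", "A", "T", NA),
    high_level = c("Other Ethnic Groups", "White", "Other Ethnic Groups",
                   "Unknown"),
    provenance = c("GDPPR_NHS", "GDPPR_NHS", "HES", "NONE"),
    had_conflict = FALSE, n_distinct_informative_codes = 1L,
    had_any_record = TRUE)
  aud <- discrepancy_audit(res, cb, "SDE", "CENSUS_2011")
  expect_setequal(aud$letters, c("R", "T"))
  expect_identical(aud$n_affected, 2L)
  expect_setequal(aud$affected$person_id, c("p1", "p3"))

  # brute force: recompute both aggregations per person and compare
  lettered <- res[!is.na(res$nhs_letter), ]
  brute <- lettered$person_id[
    map_nhs_to_high_level(cb, lettered$nhs_letter, "SDE") !=
      map_nhs_to_high_level(cb, lettered$nhs_letter, "CENSUS_2011")]
  expect_setequal(aud$affected$person_id, brute)

  all_a <- res
  all_a$nhs_letter <- "A"
  all_a$high_level <- "White"
  expect_identical(discrepancy_audit(all_a, cb)$n_affected, 0L)
})

test_that("stratified characteristics match a hand tally", {
  persons <- tibble::tibble(
    person_id = c("p1", "p2", "p3", "p4"),
    age = c(20L, 30L, 40L, 50L),
    sex = c("F", "M", "F", "M"),
    imd_decile = c(1L, 2L, NA, 4L),
    region = c("London", "London", "South East", NA),
    cm_diabetes = c(TRUE, FALSE, FALSE, TRUE),
    died = c(FALSE, FALSE, TRUE, FALSE))
  res <- make_resolved(c("GDPPR_SNOMED", "GDPPR_NHS", "HES", "NONE"))
  res$person_id <- persons$person_id
  tab <- characteristics_table(persons, res)

  n_row <- function(stratum) {
    tab$n[tab$stratum == stratum & tab$variable == "n"]
  }
  expect_identical(n_row("GDPPR"), 2L)
  expect_identical(n_row("HES"), 1L)
  expect_identical(n_row("NOT_STATED_OR_UNRECORDED"), 1L)
  expect_identical(n_row("TOTAL"), 4L)
  # strata partition the cohort
  expect_identical(n_row("GDPPR") + n_row("HES") +
                     n_row("NOT_STATED_OR_UNRECORDED"), n_row("TOTAL"))

  gd <- tab[tab$stratum == "GDPPR", ]
  expect_identical(gd$n[gd$variable == "sex" & gd$level == "F"], 1L)
  expect_identical(gd$pct[gd$variable == "sex" & gd$level == "F"], 50.0)
  expect_identical(gd$value[gd$variable == "age" & gd$level == "mean"], 25)
  expect_identical(
    gd$n[gd$variable == "cm_diabetes"], 1L)
  tot <- tab[tab$stratum == "TOTAL", ]
  expect_identical(tot$value[tot$variable == "age" & tot$level == "median"],
                   35)
  expect_identical(tot$n[tot$variable == "age_band" & tot$level == "18-29"],
                   1L)
  expect_identical(tot$n[tot$variable == "imd_decile" &
                           tot$level == "Missing"], 1L)

  # an empty stratum yields zero counts, not errors
  res2 <- make_resolved(rep("GDPPR_NHS", 4))
  res2$person_id <- persons$person_id
  tab2 <- characteristics_table(persons, res2)
  expect_identical(tab2$n[tab2$stratum == "HES" & tab2$variable == "n"], 0L)
  expect_true(all(is.na(tab2$pct[tab2$stratum == "HES" &
                                   tab2$variable == "sex"])))
})

test_that("census comparison returns signed percentage-point differences", {
  obs <- c(White = 0.773, Mixed = 0.022)
  expect_identical(census_comparison(obs, obs),
                   c(White = 0, Mixed = 0))
  got <- census_comparison(c(White = 0.773), c(White = 0.810))
  expect_equal(got, c(White = -3.7))
  expect_error(census_comparison(c(White = 1), c(Mixed = 1)),
               "same groups")
  expect_error(census_comparison(unname(c(0.5)), c(White = 0.5)),
               "named")
})

test_that("percentages round half away from zero at one decimal", {
  expect_identical(round_half_up(0.25, 1), 0.3)
  expect_identical(round_half_up(0.24, 1), 0.2)
  expect_identical(round_half_up(-0.25, 1), -0.3)
  expect_identical(round_half_up(52.147, 1), 52.1)
  expect_identical(round_half_up(51.15, 1), 51.2)
})

test_that("the assembled report carries every block and serialises", {
  cb <- fixture_codebook()
  coh <- random_cohort(60, cb, seed = 31)
  res <- harmonise_cohort(coh$persons, coh$gdppr, coh$hes, cb)
  rep <- audit_report(coh$persons, res, coh$gdppr, coh$hes, cb,
                      reference_proportions = c(
                        "White" = 0.81, "Mixed" = 0.029,
                        "Asian/Asian British" = 0.095,
                        "Black/African/Caribbean/Black British" = 0.04,
                        "Other Ethnic Groups" = 0.021, "Unknown" = 0.005))
  expect_s3_class(rep, "audit_report")
  expect_true(all(c("completeness", "multiplicity", "pair_table_gdppr",
                    "pair_table_hes", "granularity", "discrepancy",
                    "characteristics", "descriptors", "census_comparison")
                  %in% names(rep)))
  json <- withr::local_tempfile(fileext = ".json")
  md <- withr::local_tempfile(fileext = ".md")
  write_audit_json(rep, json)
  write_audit_markdown(rep, md)
  parsed <- jsonlite::read_json(json)
  expect_equal(parsed$completeness$n_total, nrow(res))
  expect_true(file.size(md) > 0)

  skipped <- audit_report(coh$persons, res, coh$gdppr, coh$hes, cb,
                          skip_descriptors = TRUE)
  expect_null(skipped$descriptors)
})
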