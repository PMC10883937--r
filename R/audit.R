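#' Round half away from zero
#'
#' Percentages in reports are rounded half-up to a fixed number of decimals
#' (so 0.25 -> 0.3 at one decimal), matching the usual presentation style of
#' descriptive epidemiology tables, rather than using banker's rounding.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

pct_of <- function(num, den, digits = 1) {
  ifelse(den > 0, round_half_up(100 * num / den, digits), NA_real_)
}

#' Completeness summary of a resolved cohort
#'
#' Reports how many persons obtained their ethnicity from each source stage,
#' completeness before and after the hospital-record fallback, and
#' missingness under both definitions: *strict* (no ethnicity record in
#' either source) and *pooled* (no record, or only non-informative "not
#' stated"/"not known" codes).
#'
#' @param resolved Output of [harmonise_cohort()].
#' @return A list of counts and one-decimal percentages, with a
#'   `by_provenance` tibble.
#' @export
completeness_summary <- function(resolved) {
  n <- nrow(resolved)
  prov_levels <- c(names(resolution_stages()), "NONE")
  by_prov <- tibble(provenance = prov_levels) |>
    dplyr::left_join(
      dplyr::count(resolved, .data$provenance),
      by = "provenance") |>
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0L),
                  pct = pct_of(.data$n, !!n))
  n_gdppr <- sum(resolved$provenance %in% c("GDPPR_SNOMED", "GDPPR_NHS"))
  n_post <- sum(resolved$provenance != "NONE")
  none <- resolved$provenance == "NONE"
  n_strict <- sum(none & !resolved$had_any_record)
  n_not_stated <- sum(none & resolved$had_any_record)
  list(
    n_total = n,
    by_provenance = by_prov,
    n_any_record = sum(resolved$had_any_record),
    pct_any_record = pct_of(sum(resolved$had_any_record), n),
    n_complete_gdppr = n_gdppr,
    pct_complete_gdppr = pct_of(n_gdppr, n),
    n_complete_post_linkage = n_post,
    pct_complete_post_linkage = pct_of(n_post, n),
    n_missing_strict = n_strict,
    pct_missing_strict = pct_of(n_strict, n),
    n_not_stated = n_not_stated,
    pct_not_stated = pct_of(n_not_stated, n),
    n_missing_pooled = sum(none),
    pct_missing_pooled = pct_of(sum(none), n)
  )
}

# Distinct letters per person for one stream of letter-annotated records.
distinct_letters_per_person <- function(ann, include_z = TRUE) {
  ann <- ann[!is.na(ann$letter), , drop = FALSE]
  denominator_ids <- unique(ann$person_id)
  if (!include_z) ann <- ann[ann$letter != "Z", , drop = FALSE]
  sets <- ann |>
    dplyr::distinct(.data$person_id, .data$letter) |>
    dplyr::count(.data$person_id, name = "k")
  list(denominator_ids = denominator_ids, sets = sets)
}

#' Rates of multiple differing ethnicity codes per person
#'
#' For each record stream — letter-coded primary-care records, concept-coded
#' primary-care records converted to letters, and hospital records — computes
#' the fraction of persons holding at least two distinct letter-level codes
#' among persons holding at least one code in that stream. With
#' `include_z = FALSE` the "not stated" code is dropped from each person's
#' code set before counting (denominators are unchanged).
#'
#' @param gdppr,hes Record tables.
#' @param cb A `codebook`.
#' @param include_z Keep `Z` in the per-person distinct-code sets?
#' @return A tibble: `stream`, `include_z`, `n_persons`, `n_multiple`,
#'   `rate`, `pct`.
#' @export
multiplicity_rates <- function(gdppr, hes, cb, include_z = TRUE) {
  g <- annotate_letters(gdppr, cb)
  h <- annotate_letters(hes, cb, coding_system = "NHS")
  streams <- list(
    gdppr_nhs = g[g$coding_system != "SNOMED", , drop = FALSE],
    gdppr_snomed = g[g$coding_system == "SNOMED", , drop = FALSE],
    hes = h
  )
  purrr::map_dfr(names(streams), function(s) {
    d <- distinct_letters_per_person(streams[[s]], include_z = include_z)
    n_pers <- length(d$denominator_ids)
    n_mult <- sum(d$sets$k >= 2)
    tibble(stream = s, include_z = include_z,
           n_persons = n_pers, n_multiple = n_mult,
           rate = if (n_pers > 0) n_mult / n_pers else NA_real_,
           pct = pct_of(n_mult, n_pers))
  })
}

#' Co-occurring code-pair table for one record stream
#'
#' Converts one stream's records to NHS letters and, for every person, adds a
#' count of one for each unordered pair of distinct letters in their record —
#' a person with three distinct codes contributes all three pairings. The
#' table total therefore equals the sum over persons of `choose(k, 2)` where
#' `k` is the person's number of distinct letters.
#'
#' @param records One stream's record table (primary-care records may mix
#'   concept- and letter-coded rows; hospital records are letters/numerals).
#' @param cb A `codebook`.
#' @return A tibble `letter_a`, `letter_b` (with `letter_a < letter_b`),
#'   `count`, sorted by decreasing count.
#' @export
cooccurrence_pairs <- function(records, cb) {
  ann <- annotate_letters(records, cb)
  ann <- ann[!is.na(ann$letter), , drop = FALSE]
  empty <- tibble(letter_a = character(), letter_b = character(),
                  count = integer())
  if (nrow(ann) == 0) return(empty)
  sets <- ann |>
    dplyr::distinct(.data$person_id, .data$letter) |>
    dplyr::arrange(.data$person_id, .data$letter)
  by_person <- split(sets$letter, sets$person_id)
  pairs <- purrr::map(by_person, function(ls) {
    if (length(ls) < 2) return(NULL)
    cmb <- utils::combn(ls, 2)
    tibble(letter_a = cmb[1, ], letter_b = cmb[2, ])
  })
  pairs <- dplyr::bind_rows(pairs)
  if (nrow(pairs) == 0) return(empty)
  pairs |>
    dplyr::count(.data$letter_a, .data$letter_b, name = "count") |>
    dplyr::arrange(dplyr::desc(.data$count), .data$letter_a, .data$letter_b)
}

#' Granularity: concept usage against the codebook
#'
#' Counts how many of the codebook's concept codes are ever used. Two
#' definitions of "used" are supported: `"any"` counts every concept
#' appearing in any concept-coded record; `"resolved"` counts only each
#' person's selected concept under the within-source strategy (the
#' most-recent concept by default), which can shrink the used set because
#' superseded records no longer contribute.
#'
#' @param gdppr Primary-care record table.
#' @param cb A `codebook`.
#' @param used_definition `"any"` or `"resolved"`.
#' @param strategy Within-person selection strategy for
#'   `used_definition = "resolved"`.
#' @return A list: `n_defined`, `n_used`, `n_unused`, `pct_used`,
#'   `used_concepts`, and `per_letter_top` (up to five most frequently used
#'   concepts per NHS letter with person counts).
#' @export
granularity_summary <- function(gdppr, cb,
                                used_definition = c("any", "resolved"),
                                strategy = c("MOST_RECENT",
                                             "MOST_FREQUENT")) {
  used_definition <- match.arg(used_definition)
  strategy <- match.arg(strategy)
  ann <- annotate_letters(gdppr, cb)
  conc <- ann[ann$coding_system == "SNOMED" & !is.na(ann$letter), ,
              drop = FALSE]
  used <- if (used_definition == "any" || nrow(conc) == 0) {
    unique(conc$concept_code)
  } else {
    date_key <- as.numeric(conc$record_date)
    date_key[is.na(date_key)] <- -Inf
    conc$.date_key <- date_key
    if (strategy == "MOST_RECENT") {
      sel <- conc |>
        dplyr::arrange(.data$person_id, -.data$.date_key, .data$code) |>
        dplyr::distinct(.data$person_id, .keep_all = TRUE)
    } else {
      per_code <- conc |>
        dplyr::group_by(.data$person_id, .data$concept_code) |>
        dplyr::summarise(n = dplyr::n(), latest = max(.data$.date_key),
                         .groups = "drop")
      sel <- per_code |>
        dplyr::arrange(.data$person_id, -.data$n, -.data$latest,
                       .data$concept_code) |>
        dplyr::distinct(.data$person_id, .keep_all = TRUE)
    }
    unique(sel$concept_code)
  }
  n_def <- nrow(cb$concepts)
  n_used <- length(used)
  per_concept <- conc |>
    dplyr::distinct(.data$person_id, .data$concept_code, .data$letter) |>
    dplyr::count(.data$letter, .data$concept_code, name = "n_persons")
  per_letter_top <- per_concept |>
    dplyr::group_by(.data$letter) |>
    dplyr::arrange(dplyr::desc(.data$n_persons), .data$concept_code,
                   .by_group = TRUE) |>
    dplyr::slice_head(n = 5) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::ungroup() |>
    dplyr::left_join(cb$concepts[, c("concept_code", "label")],
                     by = "concept_code") |>
    dplyr::select("letter", "rank", "concept_code", "label", "n_persons")
  list(
    n_defined = n_def,
    n_used = n_used,
    n_unused = n_def - n_used,
    pct_used = pct_of(n_used, n_def),
    used_definition = used_definition,
    used_concepts = sort(used),
    per_letter_top = per_letter_top
  )
}

#' Descriptor diversity of the concepts in use
#'
#' Tallies, over the set of used concepts, how many labels carry each
#' descriptor flag (ethnicity/race term, religion, geographical region,
#' language). Flags overlap, so percentages need not sum to 100.
#'
#' @param cb A `codebook` whose concepts carry descriptor flag columns.
#' @param used_concepts Character vector of concept codes in use.
#' @return A tibble: `flag`, `n_used`, `n_flagged`, `pct`.
#' @export
descriptor_prevalence <- function(cb, used_concepts) {
  used <- cb$concepts[cb$concepts$concept_code %in% used_concepts, ,
                      drop = FALSE]
  n_used <- nrow(used)
  if (n_used == 0) {
    warning("no used concepts; descriptor fractions are undefined",
            call. = FALSE)
  }
  cols <- stats::setNames(flag_columns(), descriptor_flag_names())
  purrr::map_dfr(names(cols), function(f) {
    n_flag <- if (n_used == 0) 0L else sum(used[[cols[[f]]]])
    tibble(flag = f, n_used = n_used, n_flagged = n_flag,
           pct = if (n_used == 0) 0 else pct_of(n_flag, n_used))
  })
}

#' Persons whose high-level group depends on the aggregation dialect
#'
#' Identifies the letters on which two dialects disagree and the resolved
#' persons carrying those letters — exactly the individuals whose published
#' high-level ethnicity would change if the alternative census convention
#' were used.
#'
#' @param resolved Output of [harmonise_cohort()].
#' @param cb A `codebook`.
#' @param dialect_a,dialect_b Dialect names to compare.
#' @return A list: `letters`, `n_affected`, `pct_affected` (of resolved
#'   persons with an informative letter), and an `affected` tibble with both
#'   aggregations per person.
#' @export
discrepancy_audit <- function(resolved, cb, dialect_a = "SDE",
                              dialect_b = "CENSUS_2011") {
  letters <- list_dialect_discrepancies(cb, dialect_a, dialect_b)
  has_letter <- !is.na(resolved$nhs_letter)
  hit <- has_letter & resolved$nhs_letter %in% letters
  affected <- resolved[hit, c("person_id", "nhs_letter"), drop = FALSE]
  if (nrow(affected) > 0) {
    affected$high_level_a <- map_nhs_to_high_level(cb, affected$nhs_letter,
                                                   dialect_a)
    affected$high_level_b <- map_nhs_to_high_level(cb, affected$nhs_letter,
                                                   dialect_b)
  } else {
    affected$high_level_a <- character()
    affected$high_level_b <- character()
  }
  list(
    dialect_a = dialect_a, dialect_b = dialect_b,
    letters = letters,
    n_affected = sum(hit),
    pct_affected = pct_of(sum(hit), sum(has_letter)),
    affected = tibble::as_tibble(affected)
  )
}

age_bands <- function(age) {
  cut(age, breaks = c(0, 18, 30, 40, 50, 60, 70, 80, 90, Inf),
      labels = c("0-17", "18-29", "30-39", "40-49", "50-59", "60-69",
                 "70-79", "80-89", "90+"),
      right = FALSE)
}

#' Stratified characteristics of the cohort by ethnicity source
#'
#' Summarises demographics and comorbidity flags across four strata: persons
#' whose ethnicity came from primary care, from the hospital fallback, the
#' not-stated/unrecorded group, and the whole cohort. Persons whose only
#' code was "not stated" fall in the third stratum, mirroring the convention
#' of excluding them from the recorded strata.
#'
#' @param persons Person table (must include `age`, `sex`; `region`,
#'   `imd_decile`, `died` and logical `cm_*` comorbidity columns are
#'   summarised when present).
#' @param resolved Output of [harmonise_cohort()].
#' @return A long tibble: `stratum`, `variable`, `level`, `n`, `pct`,
#'   `value` (numeric summaries such as the age mean use `value`).
#' @export
characteristics_table <- function(persons, resolved) {
  dat <- dplyr::inner_join(persons, resolved, by = "person_id")
  dat$stratum <- dplyr::case_when(
    dat$provenance %in% c("GDPPR_SNOMED", "GDPPR_NHS") ~ "GDPPR",
    dat$provenance == "HES" ~ "HES",
    TRUE ~ "NOT_STATED_OR_UNRECORDED"
  )
  strata <- list(
    GDPPR = dat[dat$stratum == "GDPPR", , drop = FALSE],
    HES = dat[dat$stratum == "HES", , drop = FALSE],
    NOT_STATED_OR_UNRECORDED =
      dat[dat$stratum == "NOT_STATED_OR_UNRECORDED", , drop = FALSE],
    TOTAL = dat
  )
  cm_cols <- grep("^cm_", names(persons), value = TRUE)

  summarise_stratum <- function(d, name) {
    denom <- nrow(d)
    rows <- list(tibble(variable = "n", level = "n", n = denom,
                        pct = NA_real_, value = NA_real_))
    cat_block <- function(variable, x, levels) {
      x <- as.character(x)
      x[is.na(x)] <- "Missing"
      lv <- c(levels, if (any(x == "Missing")) "Missing")
      purrr::map_dfr(lv, function(l) {
        k <- sum(x == l)
        tibble(variable = variable, level = l, n = k,
               pct = pct_of(k, denom), value = NA_real_)
      })
    }
    num_block <- function(variable, x) {
      x <- x[!is.na(x)]
      stats_v <- c(mean = if (length(x)) mean(x) else NA_real_,
                   sd = if (length(x) > 1) stats::sd(x) else NA_real_,
                   median = if (length(x)) stats::median(x) else NA_real_,
                   min = if (length(x)) min(x) else NA_real_,
                   max = if (length(x)) max(x) else NA_real_)
      tibble(variable = variable, level = names(stats_v), n = NA_integer_,
             pct = NA_real_, value = unname(stats_v))
    }
    rows <- c(rows, list(
      cat_block("sex", d$sex, c("F", "M")),
      num_block("age", d$age),
      cat_block("age_band", age_bands(d$age),
                levels(age_bands(integer())))
    ))
    if ("imd_decile" %in% names(d)) {
      rows <- c(rows, list(cat_block("imd_decile", d$imd_decile,
                                     as.character(1:10))))
    }
    if ("region" %in% names(d)) {
      rows <- c(rows, list(cat_block("region", d$region,
                                     sort(unique(stats::na.omit(dat$region))))))
    }
    flag_block <- function(variable, x) {
      k <- sum(x, na.rm = TRUE)
      tibble(variable = variable, level = "TRUE", n = k,
             pct = pct_of(k, denom), value = NA_real_)
    }
    if ("died" %in% names(d)) {
      rows <- c(rows, list(flag_block("died", d$died)))
    }
    for (cm in cm_cols) {
      rows <- c(rows, list(flag_block(cm, d[[cm]])))
    }
    out <- dplyr::bind_rows(rows)
    out$stratum <- name
    out[, c("stratum", "variable", "level", "n", "pct", "value")]
  }

  purrr::map_dfr(names(strata), function(s) summarise_stratum(strata[[s]], s))
}

#' Signed differences between observed and reference group proportions
#'
#' Compares a cohort's high-level group distribution against user-supplied
#' reference proportions (for example census estimates), returning
#' observed-minus-reference differences in percentage points.
#'
#' @param observed,reference Named numeric vectors of proportions over the
#'   same set of groups.
#' @return Named numeric vector of signed differences in percentage points,
#'   in the order of `observed`.
#' @export
census_comparison <- function(observed, reference) {
  if (is.null(names(observed)) || is.null(names(reference)) ||
      !setequal(names(observed), names(reference))) {
    stop("observed and reference must be named over the same groups",
         call. = FALSE)
  }
  diff <- (observed - reference[names(observed)]) * 100
  stats::setNames(as.numeric(diff), names(observed))
}

#' Assemble the full audit report
#'
#' Runs every audit block on a resolved cohort and its source record tables:
#' completeness, multiplicity (with and without `Z`), co-occurring pair
#' tables per stream, granularity, descriptor diversity, the
#' dialect-discrepancy audit, stratified characteristics, and (when reference
#' proportions are supplied) the census comparison.
#'
#' @param persons Person table.
#' @param resolved Output of [harmonise_cohort()].
#' @param gdppr,hes Record tables.
#' @param cb A `codebook`.
#' @param dialect_pair Two dialect names for the discrepancy audit.
#' @param used_definition,strategy Passed to [granularity_summary()].
#' @param reference_proportions Optional named proportions over the six
#'   high-level groups for [census_comparison()].
#' @param skip_descriptors Omit the descriptor block.
#' @param small_cell_threshold Optional integer; pair-table counts below it
#'   are suppressed (reported as `NA`). Off by default.
#' @return A list of class `audit_report`.
#' @export
audit_report <- function(persons, resolved, gdppr, hes, cb,
                         dialect_pair = c("SDE", "CENSUS_2011"),
                         used_definition = "any",
                         strategy = "MOST_RECENT",
                         reference_proportions = NULL,
                         skip_descriptors = FALSE,
                         small_cell_threshold = NULL) {
  gran <- granularity_summary(gdppr, cb, used_definition = used_definition,
                              strategy = strategy)
  suppress <- function(tbl) {
    if (!is.null(small_cell_threshold)) {
      tbl$count[tbl$count < small_cell_threshold] <- NA_integer_
    }
    tbl
  }
  rep <- list(
    completeness = completeness_summary(resolved),
    multiplicity = dplyr::bind_rows(
      multiplicity_rates(gdppr, hes, cb, include_z = TRUE),
      multiplicity_rates(gdppr, hes, cb, include_z = FALSE)
    ),
    pair_table_gdppr = suppress(cooccurrence_pairs(gdppr, cb)),
    pair_table_hes = suppress(cooccurrence_pairs(hes, cb)),
    granularity = gran[c("n_defined", "n_used", "n_unused", "pct_used",
                         "used_definition", "per_letter_top")],
    discrepancy = discrepancy_audit(resolved, cb, dialect_pair[1],
                                    dialect_pair[2]),
    characteristics = characteristics_table(persons, resolved)
  )
  if (!skip_descriptors) {
    rep$descriptors <- descriptor_prevalence(cb, gran$used_concepts)
  }
  if (!is.null(reference_proportions)) {
    prov_rec <- resolved[resolved$provenance != "NONE", , drop = FALSE]
    obs <- table(factor(prov_rec$high_level, levels = high_level_groups()))
    obs <- obs / max(1, sum(obs))
    rep$census_comparison <- as.list(census_comparison(
      stats::setNames(as.numeric(obs), names(obs))[names(reference_proportions)],
      reference_proportions))
  }
  structure(rep, class = "audit_report")
}

#' @export
print.audit_report <- function(x, ...) {
  comp <- x$completeness
  cat("<audit_report>\n")
  cat(sprintf("  cohort size:          %d\n", comp$n_total))
  cat(sprintf("  complete (GDPPR):     %d (%.1f%%)\n",
              comp$n_complete_gdppr, comp$pct_complete_gdppr))
  cat(sprintf("  complete (post-link): %d (%.1f%%)\n",
              comp$n_complete_post_linkage, comp$pct_complete_post_linkage))
  cat(sprintf("  missing (strict):     %d (%.1f%%)\n",
              comp$n_missing_strict, comp$pct_missing_strict))
  cat(sprintf("  missing (pooled):     %d (%.1f%%)\n",
              comp$n_missing_pooled, comp$pct_missing_pooled))
  cat(sprintf("  concepts used:        %d / %d (%.1f%%)\n",
              x$granularity$n_used, x$granularity$n_defined,
              x$granularity$pct_used))
  invisible(x)
}

#' Write an audit report as JSON
#'
#' @param report An `audit_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_audit_json <- function(report, path) {
  out <- unclass(report)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

md_table <- function(df) {
  df <- as.data.frame(df)
  fmt <- function(x) {
    if (is.numeric(x)) ifelse(is.na(x), "", format(x, trim = TRUE)) else
      ifelse(is.na(x), "", as.character(x))
  }
  cells <- vapply(df, fmt, character(nrow(df)))
  if (nrow(df) == 1) cells <- matrix(cells, nrow = 1)
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  body <- apply(cells, 1, function(r) paste0("| ", paste(r, collapse = " | "),
                                             " |"))
  c(header, sep, body)
}

#' Write an audit report as a markdown document
#'
#' @param report An `audit_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_audit_markdown <- function(report, path) {
  comp <- report$completeness
  lines <- c(
    "# Ethnicity data audit report", "",
    "## Completeness", "",
    sprintf("- Cohort size: %d", comp$n_total),
    sprintf("- Any ethnicity record: %d (%.1f%%)", comp$n_any_record,
            comp$pct_any_record),
    sprintf("- Resolved from primary care: %d (%.1f%%)",
            comp$n_complete_gdppr, comp$pct_complete_gdppr),
    sprintf("- Resolved after hospital fallback: %d (%.1f%%)",
            comp$n_complete_post_linkage, comp$pct_complete_post_linkage),
    sprintf("- Missing, strict (no record anywhere): %d (%.1f%%)",
            comp$n_missing_strict, comp$pct_missing_strict),
    sprintf("- Not stated / not known only: %d (%.1f%%)", comp$n_not_stated,
            comp$pct_not_stated),
    sprintf("- Missing, pooled: %d (%.1f%%)", comp$n_missing_pooled,
            comp$pct_missing_pooled),
    "", "### By provenance", "",
    md_table(comp$by_provenance), "",
    "## Multiple records", "",
    md_table(report$multiplicity), "",
    "## Co-occurring code pairs (primary care, top 20)", "",
    md_table(utils::head(report$pair_table_gdppr, 20)), "",
    "## Co-occurring code pairs (hospital, top 20)", "",
    md_table(utils::head(report$pair_table_hes, 20)), "",
    "## Granularity", "",
    sprintf("- Concepts defined: %d", report$granularity$n_defined),
    sprintf("- Concepts used (%s definition): %d (%.1f%%)",
            report$granularity$used_definition, report$granularity$n_used,
            report$granularity$pct_used),
    sprintf("- Concepts never used: %d", report$granularity$n_unused),
    "", "### Five most used concepts per letter", "",
    md_table(report$granularity$per_letter_top), ""
  )
  if (!is.null(report$descriptors)) {
    lines <- c(lines, "## Descriptor diversity of used concepts", "",
               md_table(report$descriptors), "")
  }
  disc <- report$discrepancy
  lines <- c(lines,
    sprintf("## Dialect discrepancies (%s vs %s)", disc$dialect_a,
            disc$dialect_b), "",
    sprintf("- Letters affected: %s",
            if (length(disc$letters)) paste(disc$letters, collapse = ", ")
            else "none"),
    sprintf("- Persons affected: %d (%.1f%%)", disc$n_affected,
            disc$pct_affected),
    "", "## Characteristics by source stratum", "",
    md_table(report$characteristics), "")
  if (!is.null(report$census_comparison)) {
    cc <- tibble(group = names(report$census_comparison),
                 diff_pct_points = unlist(report$census_comparison))
    lines <- c(lines, "## Census comparison (percentage points)", "",
               md_table(cc), "")
  }
  writeLines(lines, path)
  invisible(path)
}
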