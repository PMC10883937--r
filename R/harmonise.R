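#' Apply the cohort eligibility filter
#'
#' Persons with an invalid age (below 0 or 115 and over) or missing sex are
#' excluded before any ethnicity resolution; an age of exactly 0 is valid.
#'
#' @param persons Person table with `person_id`, `age` and `sex` columns.
#' @return A list with `eligible` (the retained rows) and `exclusions`
#'   (a tibble of `person_id`, `reason` with one row per reason:
#'   `invalid_age` or `missing_sex`).
#' @export
apply_eligibility_filter <- function(persons) {
  stopifnot(all(c("person_id", "age", "sex") %in% names(persons)))
  bad_age <- is.na(persons$age) | persons$age < 0 | persons$age >= 115
  bad_sex <- is.na(persons$sex) | !(persons$sex %in% c("F", "M"))
  exclusions <- dplyr::bind_rows(
    tibble(person_id = persons$person_id[bad_age], reason = "invalid_age"),
    tibble(person_id = persons$person_id[bad_sex], reason = "missing_sex")
  )
  list(eligible = persons[!(bad_age | bad_sex), , drop = FALSE],
       exclusions = exclusions)
}

informative_letter <- function(letter) {
  !is.na(letter) & !(letter %in% non_informative_codes())
}

# Convert a stream of raw records into letter-annotated rows.
# `code` may be a concept code (coding_system == "SNOMED"), an NHS letter, or
# a legacy numeral 0-9 (translated). Unknown codes get letter NA and are
# collected by the caller.
annotate_letters <- function(records, cb, coding_system = NULL) {
  n <- nrow(records)
  if (is.null(coding_system)) {
    coding_system <- if ("coding_system" %in% names(records)) {
      records$coding_system
    } else {
      rep("NHS", n)
    }
  } else {
    coding_system <- rep(coding_system, n)
  }
  code <- as.character(records$code)
  letter <- rep(NA_character_, n)
  is_sno <- coding_system == "SNOMED"
  letter[is_sno] <- map_concept_to_nhs(cb, code[is_sno])
  is_leg <- !is_sno & code %in% cb$legacy$numeral
  letter[is_leg] <- translate_legacy(cb, code[is_leg])
  valid_letters <- c(cb$nhs_categories$letter, WHITE_UNSPECIFIED)
  is_letter <- !is_sno & !is_leg & code %in% valid_letters
  letter[is_letter] <- code[is_letter]
  concept_code <- rep(NA_character_, n)
  concept_code[is_sno] <- code[is_sno]
  tibble(
    person_id = as.character(records$person_id),
    coding_system = as.character(coding_system),
    code = code,
    concept_code = concept_code,
    letter = letter,
    informative = informative_letter(letter),
    record_date = as.Date(records$record_date)
  )
}

#' Select one record within a single person/source stream
#'
#' Non-informative records (`Z`, `X`, `99`, or codes absent from the
#' codebook) are never selected. Under `MOST_RECENT` the informative record
#' with the latest date wins; records with missing dates rank below all dated
#' records; date ties prefer concept-coded over letter-coded records and then
#' the lexicographically smallest code. Under `MOST_FREQUENT` the modal
#' informative letter wins, ties going to the letter recorded most recently;
#' the returned record is the most recent one carrying the winning letter.
#'
#' @param records Letter-annotated records for one person and one source:
#'   columns `code`, `letter`, `record_date`, optionally `coding_system`.
#' @param strategy `"MOST_RECENT"` or `"MOST_FREQUENT"`.
#' @return A one-row tibble, or `NULL` when no informative record exists.
#' @export
select_within_source <- function(records,
                                 strategy = c("MOST_RECENT",
                                              "MOST_FREQUENT")) {
  strategy <- match.arg(strategy)
  if (is.null(records) || nrow(records) == 0) return(NULL)
  if (!"informative" %in% names(records)) {
    records$informative <- informative_letter(records$letter)
  }
  inf <- records[records$informative, , drop = FALSE]
  if (nrow(inf) == 0) return(NULL)
  if (!"coding_system" %in% names(inf)) inf$coding_system <- "NHS"
  date_key <- as.numeric(inf$record_date)
  date_key[is.na(date_key)] <- -Inf
  concept_first <- ifelse(inf$coding_system == "SNOMED", 0L, 1L)
  if (strategy == "MOST_RECENT") {
    ord <- order(-date_key, concept_first, inf$code)
    return(inf[ord[1], , drop = FALSE])
  }
  # MOST_FREQUENT at letter level
  tab <- table(inf$letter)
  modal <- names(tab)[tab == max(tab)]
  if (length(modal) > 1) {
    latest <- vapply(modal, function(l) {
      max(date_key[inf$letter == l])
    }, numeric(1))
    modal <- modal[order(-latest, modal)][1]
  }
  cand <- inf[inf$letter == modal, , drop = FALSE]
  dk <- date_key[inf$letter == modal]
  cf <- concept_first[inf$letter == modal]
  ord <- order(-dk, cf, cand$code)
  cand[ord[1], , drop = FALSE]
}

resolution_stages <- function() {
  c("GDPPR_SNOMED" = 1L, "GDPPR_NHS" = 2L, "HES" = 3L)
}

#' Resolve one person's ethnicity through the source-prioritisation tree
#'
#' Sources are consulted in fixed priority order: (1) concept-coded
#' primary-care records, (2) letter-coded primary-care records, (3) hospital
#' records (letters or legacy numerals); a later stage is consulted only when
#' every earlier stage holds no informative code. Persons whose records are
#' all non-informative (or who have no records) resolve to Unknown with
#' provenance `NONE`.
#'
#' @param gdppr_records Primary-care records for one person: `person_id`,
#'   `coding_system` (`"SNOMED"` or `"NHS"`), `code`, `record_date`.
#' @param hes_records Hospital records for the same person: `person_id`,
#'   `code`, `record_date`.
#' @param cb A `codebook`.
#' @param dialect Aggregation dialect for the high-level group.
#' @param strategy Within-source selection strategy, see
#'   [select_within_source()].
#' @param hes_fallback If `FALSE`, hospital records are never consulted.
#' @param z_blocks_fallback If `TRUE`, a "not stated" (Z) code in primary
#'   care is taken as the person's answer and hospital records are not
#'   consulted for them; the default treats Z as non-informative at every
#'   stage, so any informative source can still supply the ethnicity.
#' @return A one-row tibble: `person_id`, `concept_code`, `nhs_letter`,
#'   `high_level`, `provenance`, `had_conflict`,
#'   `n_distinct_informative_codes`, `had_any_record`.
#' @export
resolve_person <- function(gdppr_records, hes_records, cb,
                           dialect = "SDE",
                           strategy = c("MOST_RECENT", "MOST_FREQUENT"),
                           hes_fallback = TRUE,
                           z_blocks_fallback = FALSE) {
  strategy <- match.arg(strategy)
  check_dialect(cb, dialect)
  if (is.null(gdppr_records)) gdppr_records <- tibble(person_id = character(),
                                                      coding_system = character(),
                                                      code = character(),
                                                      record_date = as.Date(character()))
  if (is.null(hes_records)) hes_records <- tibble(person_id = character(),
                                                  code = character(),
                                                  record_date = as.Date(character()))
  pid <- unique(c(gdppr_records$person_id, hes_records$person_id))
  if (length(pid) > 1) {
    stop("resolve_person expects records for a single person", call. = FALSE)
  }
  if (length(pid) == 0) pid <- NA_character_

  g <- annotate_letters(gdppr_records, cb)
  h <- annotate_letters(hes_records, cb, coding_system = "NHS")
  stages <- list(g[g$coding_system == "SNOMED", , drop = FALSE],
                 g[g$coding_system != "SNOMED", , drop = FALSE],
                 h)

  all_rows <- dplyr::bind_rows(stages)
  n_informative <- length(unique(all_rows$letter[all_rows$informative]))
  had_any <- nrow(all_rows) > 0

  block_hes <- z_blocks_fallback &&
    any(g$letter %in% "Z") && !any(g$informative)
  max_stage <- if (!hes_fallback || block_hes) 2L else 3L

  chosen <- NULL
  stage_used <- NA_integer_
  for (k in seq_len(max_stage)) {
    chosen <- select_within_source(stages[[k]], strategy)
    if (!is.null(chosen)) {
      stage_used <- k
      break
    }
  }

  if (is.null(chosen)) {
    return(tibble(
      person_id = pid, concept_code = NA_character_,
      nhs_letter = NA_character_, high_level = "Unknown",
      provenance = "NONE", had_conflict = n_informative >= 2,
      n_distinct_informative_codes = n_informative,
      had_any_record = had_any
    ))
  }
  tibble(
    person_id = pid,
    concept_code = chosen$concept_code,
    nhs_letter = chosen$letter,
    high_level = map_nhs_to_high_level(cb, chosen$letter, dialect),
    provenance = names(resolution_stages())[stage_used],
    had_conflict = n_informative >= 2,
    n_distinct_informative_codes = n_informative,
    had_any_record = had_any
  )
}

#' Resolve ethnicity for a whole cohort
#'
#' Vectorised equivalent of applying [resolve_person()] to every eligible
#' person: the eligibility filter runs first, then each person is resolved
#' through the source-prioritisation tree. Codes absent from the codebook are
#' treated as non-informative and collected in the `unknown_codes` attribute
#' rather than aborting the run.
#'
#' @param persons Person table (`person_id`, `age`, `sex`, ...); duplicate
#'   `person_id` rows are an error.
#' @param gdppr,hes Record tables as produced by [generate_records()] or
#'   read from CSV.
#' @param cb A `codebook`.
#' @inheritParams resolve_person
#' @return A tibble with one row per eligible person (columns as
#'   [resolve_person()]), with attributes `exclusions` (the eligibility log)
#'   and `unknown_codes` (distinct unresolvable codes seen).
#' @export
harmonise_cohort <- function(persons, gdppr, hes, cb,
                             dialect = "SDE",
                             strategy = c("MOST_RECENT", "MOST_FREQUENT"),
                             hes_fallback = TRUE,
                             z_blocks_fallback = FALSE) {
  strategy <- match.arg(strategy)
  check_dialect(cb, dialect)
  if (anyDuplicated(persons$person_id)) {
    stop("duplicate person_id rows in person table: ",
         paste(unique(persons$person_id[duplicated(persons$person_id)])[1:5],
               collapse = ", "), call. = FALSE)
  }
  filt <- apply_eligibility_filter(persons)
  eligible <- filt$eligible

  g <- annotate_letters(gdppr, cb)
  h <- annotate_letters(hes, cb, coding_system = "NHS")
  g$stage <- ifelse(g$coding_system == "SNOMED", 1L, 2L)
  h$stage <- 3L
  recs <- dplyr::bind_rows(g, h)
  recs <- recs[recs$person_id %in% eligible$person_id, , drop = FALSE]

  unknown <- sort(unique(recs$code[is.na(recs$letter)]))

  # per-person summaries over all streams
  summ <- recs |>
    dplyr::group_by(.data$person_id) |>
    dplyr::summarise(
      had_any_record = dplyr::n() > 0,
      n_distinct_informative_codes =
        length(unique(.data$letter[.data$informative])),
      gdppr_has_z = any(.data$stage < 3L & .data$letter %in% "Z"),
      gdppr_has_informative = any(.data$stage < 3L & .data$informative),
      .groups = "drop"
    )

  inf <- recs[recs$informative, , drop = FALSE]
  if (!hes_fallback) inf <- inf[inf$stage < 3L, , drop = FALSE]
  if (z_blocks_fallback) {
    blocked <- summ$person_id[summ$gdppr_has_z & !summ$gdppr_has_informative]
    inf <- inf[!(inf$person_id %in% blocked & inf$stage == 3L), ,
               drop = FALSE]
  }

  chosen <- if (nrow(inf) == 0) {
    inf[0, , drop = FALSE]
  } else {
    # restrict to each person's best (lowest) stage
    inf <- inf |>
      dplyr::group_by(.data$person_id) |>
      dplyr::filter(.data$stage == min(.data$stage)) |>
      dplyr::ungroup()
    date_key <- as.numeric(inf$record_date)
    date_key[is.na(date_key)] <- -Inf
    inf$.date_key <- date_key
    inf$.concept_first <- ifelse(inf$coding_system == "SNOMED", 0L, 1L)
    if (strategy == "MOST_RECENT") {
      inf |>
        dplyr::arrange(.data$person_id, -.data$.date_key,
                       .data$.concept_first, .data$code) |>
        dplyr::distinct(.data$person_id, .keep_all = TRUE)
    } else {
      # modal letter, ties to the most recently recorded letter, then the
      # most recent record of the winning letter
      per_letter <- inf |>
        dplyr::group_by(.data$person_id, .data$letter) |>
        dplyr::summarise(n = dplyr::n(), latest = max(.data$.date_key),
                         .groups = "drop")
      winner <- per_letter |>
        dplyr::arrange(.data$person_id, -.data$n, -.data$latest,
                       .data$letter) |>
        dplyr::distinct(.data$person_id, .keep_all = TRUE) |>
        dplyr::select("person_id", "letter")
      inf |>
        dplyr::inner_join(winner, by = c("person_id", "letter")) |>
        dplyr::arrange(.data$person_id, -.data$.date_key,
                       .data$.concept_first, .data$code) |>
        dplyr::distinct(.data$person_id, .keep_all = TRUE)
    }
  }

  stage_names <- names(resolution_stages())
  resolved_some <- tibble(
    person_id = chosen$person_id,
    concept_code = chosen$concept_code,
    nhs_letter = chosen$letter,
    high_level = if (nrow(chosen) > 0) {
      map_nhs_to_high_level(cb, chosen$letter, dialect)
    } else character(),
    provenance = stage_names[chosen$stage]
  )

  out <- tibble(person_id = eligible$person_id) |>
    dplyr::left_join(resolved_some, by = "person_id") |>
    dplyr::left_join(summ, by = "person_id")
  out$high_level[is.na(out$high_level)] <- "Unknown"
  out$provenance[is.na(out$provenance)] <- "NONE"
  out$had_any_record[is.na(out$had_any_record)] <- FALSE
  out$n_distinct_informative_codes[is.na(out$n_distinct_informative_codes)] <- 0L
  out$had_conflict <- out$n_distinct_informative_codes >= 2L
  out <- out[, c("person_id", "concept_code", "nhs_letter", "high_level",
                 "provenance", "had_conflict",
                 "n_distinct_informative_codes", "had_any_record")]
  attr(out, "exclusions") <- filt$exclusions
  attr(out, "unknown_codes") <- unknown
  out
}
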