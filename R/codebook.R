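#' @importFrom rlang .data
#' @importFrom tibble tibble as_tibble
NULL

# Sentinel used when a legacy numeral identifies the high-level group (White)
# but not which of the A/B/C letters was meant.
WHITE_UNSPECIFIED <- "WHITE_UNSPECIFIED"

#' The 19 NHS A-Z ethnicity letters
#'
#' The NHS Data Dictionary records ethnicity with single-letter categories
#' aligned to the 2011 census. Nineteen letter categories exist (the letters
#' I, O, Q, U, V and Y are not assigned); `Z` ("not stated") is one of the 19
#' but carries no ethnicity information. Two further non-letter categories,
#' `X` ("not known", pre-2013) and `99` ("not known", 2013 onwards), sit
#' outside the 19.
#'
#' @param informative_only If `TRUE`, drop `Z` (and, always absent here,
#'   `X`/`99`), keeping only letters that identify an ethnic group.
#' @return Character vector of letters.
#' @export
nhs_letters <- function(informative_only = FALSE) {
  letters19 <- c("A", "B", "C", "D", "E", "F", "G", "H", "J", "K",
                 "L", "M", "N", "P", "R", "S", "T", "W", "Z")
  if (informative_only) setdiff(letters19, "Z") else letters19
}

# Categories that are recorded but identify no ethnic group.
non_informative_codes <- function() c("Z", "X", "99")

#' The six high-level ethnicity groups
#'
#' The aggregation used across UK health research: White; Mixed; Asian/Asian
#' British; Black/African/Caribbean/Black British; Other Ethnic Groups; and
#' Unknown (not always shown in publications).
#'
#' @return Character vector of the six group names.
#' @export
high_level_groups <- function() {
  c("White", "Mixed", "Asian/Asian British",
    "Black/African/Caribbean/Black British", "Other Ethnic Groups", "Unknown")
}

#' Names of the three supported aggregation dialects
#'
#' `SDE` is the algorithm used inside the secure data environment (which
#' follows the 2001 census in placing Chinese (R) and Gypsy/Irish Traveller
#' (T) under Other Ethnic Groups); `CENSUS_2011` and `CENSUS_2021` follow the
#' respective ONS census conventions (R under Asian/Asian British, T under
#' White).
#'
#' @return Character vector of dialect names.
#' @export
dialect_names <- function() c("SDE", "CENSUS_2011", "CENSUS_2021")

# Canonical NHS category table: letter, label, informative flag and the
# high-level assignment under each dialect.
default_nhs_categories <- function() {
  hl <- high_level_groups()
  white <- hl[1]; mixed <- hl[2]; asian <- hl[3]; black <- hl[4]
  other <- hl[5]; unknown <- hl[6]
  tbl <- tibble::tribble(
    ~letter, ~label,                          ~census,
    "A", "British",                           white,
    "B", "Irish",                             white,
    "C", "Any other White background",        white,
    "T", "Gypsy or Irish Traveller",          white,
    "D", "White and Black Caribbean",         mixed,
    "E", "White and Black African",           mixed,
    "F", "White and Asian",                   mixed,
    "G", "Any other Mixed background",        mixed,
    "H", "Indian",                            asian,
    "J", "Pakistani",                         asian,
    "K", "Bangladeshi",                       asian,
    "L", "Any other Asian background",        asian,
    "R", "Chinese",                           asian,
    "M", "Caribbean",                         black,
    "N", "African",                           black,
    "P", "Any other Black background",        black,
    "S", "Any other ethnic group",            other,
    "W", "Arab",                              other,
    "Z", "Not stated",                        unknown,
    "X", "Not known (prior 2013)",            unknown,
    "99", "Not known (2013 onwards)",         unknown
  )
  tbl$informative <- !(tbl$letter %in% non_informative_codes())
  # SDE convention: R and T fall under Other Ethnic Groups.
  tbl$high_level_sde <- ifelse(tbl$letter %in% c("R", "T"),
                               other, tbl$census)
  tbl$high_level_census2011 <- tbl$census
  tbl$high_level_census2021 <- tbl$census
  tbl$census <- NULL
  tbl[, c("letter", "label", "informative", "high_level_sde",
          "high_level_census2011", "high_level_census2021")]
}

# Legacy numeric ethnicity codes (used 1995/96-2000/01, still present in
# hospital data). 0 meant "White" without distinguishing A/B/C.
default_legacy_map <- function() {
  tibble::tribble(
    ~numeral, ~nhs_equivalent,
    "0", WHITE_UNSPECIFIED,
    "1", "M",
    "2", "N",
    "3", "P",
    "4", "H",
    "5", "J",
    "6", "K",
    "7", "R",
    "8", "S",
    "9", "Z"
  )
}

descriptor_flag_names <- function() {
  c("ETHNICITY_RACE", "RELIGION", "GEOGRAPHY", "LANGUAGE")
}

flag_columns <- function() {
  c("flag_ethnicity_race", "flag_religion", "flag_geography", "flag_language")
}

new_codebook <- function(concepts, nhs_categories = default_nhs_categories(),
                         legacy = default_legacy_map()) {
  dialects <- lapply(
    c(SDE = "high_level_sde",
      CENSUS_2011 = "high_level_census2011",
      CENSUS_2021 = "high_level_census2021"),
    function(col) {
      map <- stats::setNames(nhs_categories[[col]], nhs_categories$letter)
      c(map, stats::setNames("White", WHITE_UNSPECIFIED))
    }
  )
  structure(
    list(concepts = tibble::as_tibble(concepts),
         nhs_categories = tibble::as_tibble(nhs_categories),
         dialects = dialects,
         legacy = tibble::as_tibble(legacy)),
    class = "codebook"
  )
}

#' @export
print.codebook <- function(x, ...) {
  cat("<codebook>\n")
  cat("  concepts:      ", nrow(x$concepts), "\n")
  cat("  NHS categories:", nrow(x$nhs_categories),
      sprintf("(%d A-Z letters)", sum(x$nhs_categories$letter %in% nhs_letters())),
      "\n")
  cat("  dialects:      ", paste(names(x$dialects), collapse = ", "), "\n")
  cat("  legacy codes:  ", nrow(x$legacy), "\n")
  invisible(x)
}

codebook_csv_columns <- function() {
  c("level", "concept_code", "label", "nhs_category",
    "flag_ethnicity_race", "flag_religion", "flag_geography",
    "flag_language", "letter", "high_level_sde", "high_level_census2011",
    "high_level_census2021", "numeral", "nhs_equivalent")
}

#' Load a codebook from its CSV representation
#'
#' The codebook file is a single UTF-8 CSV whose `level` column distinguishes
#' three sections: `CONCEPT` rows (fine-grained terminology codes and their
#' NHS letter), `NHS` rows (the letter categories with labels and high-level
#' assignments under each dialect) and `LEGACY` rows (numeral-to-letter
#' translations for pre-2001 codes).
#'
#' @param path Path to the codebook CSV.
#' @param format Only `"standard_csv"` is supported.
#' @return A validated `codebook` object.
#' @seealso [validate_codebook()], [write_codebook()]
#' @export
load_codebook <- function(path, format = "standard_csv") {
  format <- match.arg(format, "standard_csv")
  if (!file.exists(path)) {
    stop("codebook file not found: ", path, call. = FALSE)
  }
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  missing_cols <- setdiff(codebook_csv_columns(), names(raw))
  if (length(missing_cols) > 0) {
    stop("codebook CSV is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  bad_level <- setdiff(unique(raw$level), c("CONCEPT", "NHS", "LEGACY"))
  if (length(bad_level) > 0) {
    stop("unknown level value(s) in codebook CSV: ",
         paste(bad_level, collapse = ", "), call. = FALSE)
  }

  concepts <- raw[raw$level == "CONCEPT",
                  c("concept_code", "label", "nhs_category", flag_columns())]
  for (col in flag_columns()) {
    concepts[[col]] <- tolower(trimws(concepts[[col]])) %in%
      c("true", "t", "1", "yes")
  }

  nhs <- raw[raw$level == "NHS",
             c("letter", "label", "high_level_sde", "high_level_census2011",
               "high_level_census2021")]
  nhs$informative <- !(nhs$letter %in% non_informative_codes())
  nhs <- nhs[, c("letter", "label", "informative", "high_level_sde",
                 "high_level_census2011", "high_level_census2021")]

  legacy <- raw[raw$level == "LEGACY", c("numeral", "nhs_equivalent")]

  cb <- new_codebook(concepts, nhs, legacy)
  report <- validate_codebook(cb)
  if (nrow(report) > 0) {
    stop("codebook failed validation:\n",
         paste(sprintf("  [%s] %s", report$rule, report$detail),
               collapse = "\n"),
         call. = FALSE)
  }
  cb
}

#' Write a codebook to its CSV representation
#'
#' @param cb A `codebook`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_codebook <- function(cb, path) {
  stopifnot(inherits(cb, "codebook"))
  empty <- function(n) rep(NA_character_, n)
  concept_rows <- tibble(
    level = rep("CONCEPT", nrow(cb$concepts)),
    concept_code = cb$concepts$concept_code,
    label = cb$concepts$label,
    nhs_category = cb$concepts$nhs_category,
    flag_ethnicity_race = tolower(as.character(cb$concepts$flag_ethnicity_race)),
    flag_religion = tolower(as.character(cb$concepts$flag_religion)),
    flag_geography = tolower(as.character(cb$concepts$flag_geography)),
    flag_language = tolower(as.character(cb$concepts$flag_language)),
    letter = empty(nrow(cb$concepts)),
    high_level_sde = empty(nrow(cb$concepts)),
    high_level_census2011 = empty(nrow(cb$concepts)),
    high_level_census2021 = empty(nrow(cb$concepts)),
    numeral = empty(nrow(cb$concepts)),
    nhs_equivalent = empty(nrow(cb$concepts))
  )
  nhs <- cb$nhs_categories
  nhs_rows <- tibble(
    level = rep("NHS", nrow(nhs)),
    concept_code = empty(nrow(nhs)), label = nhs$label,
    nhs_category = empty(nrow(nhs)),
    flag_ethnicity_race = empty(nrow(nhs)), flag_religion = empty(nrow(nhs)),
    flag_geography = empty(nrow(nhs)), flag_language = empty(nrow(nhs)),
    letter = nhs$letter,
    high_level_sde = nhs$high_level_sde,
    high_level_census2011 = nhs$high_level_census2011,
    high_level_census2021 = nhs$high_level_census2021,
    numeral = empty(nrow(nhs)), nhs_equivalent = empty(nrow(nhs))
  )
  leg <- cb$legacy
  leg_rows <- tibble(
    level = rep("LEGACY", nrow(leg)),
    concept_code = empty(nrow(leg)), label = empty(nrow(leg)),
    nhs_category = empty(nrow(leg)),
    flag_ethnicity_race = empty(nrow(leg)), flag_religion = empty(nrow(leg)),
    flag_geography = empty(nrow(leg)), flag_language = empty(nrow(leg)),
    letter = empty(nrow(leg)),
    high_level_sde = empty(nrow(leg)),
    high_level_census2011 = empty(nrow(leg)),
    high_level_census2021 = empty(nrow(leg)),
    numeral = leg$numeral, nhs_equivalent = leg$nhs_equivalent
  )
  out <- rbind(concept_rows, nhs_rows, leg_rows)
  readr::write_csv(out, path, na = "", progress = FALSE)
  invisible(path)
}

#' Validate a codebook against its structural invariants
#'
#' Checks that every concept maps to one of the 19 letter categories (never
#' to `X` or `99`), that concept codes are unique, that exactly the expected
#' letter set is present, that each dialect totally maps every category to
#' one of the six high-level groups with `Z`/`X`/`99` going to Unknown, that
#' the SDE and 2011-census conventions differ exactly on `{R, T}`, and that
#' the legacy map covers the numerals 0-9 with the documented equivalents.
#'
#' Violations are returned as data, not raised: a loader can decide whether
#' to abort while an auditor can report them.
#'
#' @param cb A `codebook`.
#' @return A tibble with columns `rule` and `detail`; zero rows when the
#'   codebook is valid.
#' @export
validate_codebook <- function(cb) {
  stopifnot(inherits(cb, "codebook"))
  violations <- list()
  add <- function(rule, detail) {
    violations[[length(violations) + 1]] <<- tibble(rule = rule,
                                                    detail = detail)
  }

  expected_letters <- c(nhs_letters(), "X", "99")
  got <- cb$nhs_categories$letter
  if (anyDuplicated(got)) {
    add("nhs_letters_unique",
        paste("duplicated letter(s):",
              paste(unique(got[duplicated(got)]), collapse = ", ")))
  }
  missing_l <- setdiff(expected_letters, got)
  extra_l <- setdiff(got, expected_letters)
  if (length(missing_l) > 0) {
    add("nhs_letters_complete",
        paste("missing letter(s):", paste(missing_l, collapse = ", ")))
  }
  if (length(extra_l) > 0) {
    add("nhs_letters_valid",
        paste("invalid letter(s):", paste(extra_l, collapse = ", ")))
  }

  # Concepts must point at an existing letter category, and never at the
  # "not known" categories X/99.
  cc <- cb$concepts
  if (nrow(cc) > 0) {
    dup <- unique(cc$concept_code[duplicated(cc$concept_code)])
    if (length(dup) > 0) {
      add("concept_code_unique",
          paste("duplicated concept_code(s):", paste(dup, collapse = ", ")))
    }
    bad_target <- setdiff(unique(cc$nhs_category), nhs_letters())
    for (b in bad_target) {
      offenders <- cc$concept_code[cc$nhs_category == b]
      add("concept_maps_to_valid_letter",
          sprintf("concept(s) %s map to invalid category '%s'",
                  paste(offenders, collapse = ", "), b))
    }
  }

  hl <- high_level_groups()
  for (d in names(cb$dialects)) {
    map <- cb$dialects[[d]]
    dom <- setdiff(c(expected_letters, WHITE_UNSPECIFIED), names(map))
    if (length(dom) > 0) {
      add("dialect_total",
          sprintf("dialect %s missing assignment for: %s", d,
                  paste(dom, collapse = ", ")))
    }
    bad_rng <- setdiff(unique(map), hl)
    if (length(bad_rng) > 0) {
      add("dialect_range",
          sprintf("dialect %s assigns unknown group(s): %s", d,
                  paste(bad_rng, collapse = ", ")))
    }
    for (ni in intersect(non_informative_codes(), names(map))) {
      if (!is.na(map[[ni]]) && map[[ni]] != "Unknown") {
        add("non_informative_to_unknown",
            sprintf("dialect %s maps %s to '%s', expected 'Unknown'",
                    d, ni, map[[ni]]))
      }
    }
  }

  # The SDE and 2011-census conventions must disagree exactly on R and T.
  if (all(c("SDE", "CENSUS_2011") %in% names(cb$dialects))) {
    diff <- dialect_diff_letters(cb, "SDE", "CENSUS_2011")
    if (!setequal(diff, c("R", "T"))) {
      add("sde_census2011_differ_on_RT",
          sprintf("SDE/CENSUS_2011 must differ exactly on {R,T}; found {%s}",
                  paste(sort(diff), collapse = ",")))
    }
  }

  ref <- default_legacy_map()
  leg <- cb$legacy
  if (!setequal(leg$numeral, ref$numeral)) {
    add("legacy_domain",
        paste("legacy numerals must be exactly 0-9; found:",
              paste(sort(leg$numeral), collapse = ", ")))
  } else {
    m <- merge(leg, ref, by = "numeral", suffixes = c("", "_ref"))
    bad <- m[m$nhs_equivalent != m$nhs_equivalent_ref, ]
    if (nrow(bad) > 0) {
      add("legacy_values",
          paste(sprintf("numeral %s maps to %s, expected %s", bad$numeral,
                        bad$nhs_equivalent, bad$nhs_equivalent_ref),
                collapse = "; "))
    }
  }

  if (length(violations) == 0) {
    tibble(rule = character(), detail = character())
  } else {
    dplyr::bind_rows(violations)
  }
}

# Letters (excluding the WHITE_UNSPECIFIED sentinel) whose high-level group
# differs between two dialect maps.
dialect_diff_letters <- function(cb, dialect_a, dialect_b) {
  ma <- cb$dialects[[dialect_a]]
  mb <- cb$dialects[[dialect_b]]
  letters <- setdiff(intersect(names(ma), names(mb)), WHITE_UNSPECIFIED)
  letters[ma[letters] != mb[letters]]
}

check_dialect <- function(cb, dialect_name) {
  if (!dialect_name %in% names(cb$dialects)) {
    stop("unknown dialect '", dialect_name, "'; available: ",
         paste(names(cb$dialects), collapse = ", "), call. = FALSE)
  }
  dialect_name
}

#' Map concept codes to NHS letters
#'
#' @param cb A `codebook`.
#' @param concept_code Character vector of concept codes.
#' @return Character vector of NHS letters; `NA` marks a code absent from the
#'   codebook (the unmapped signal — callers decide whether that means
#'   missing or an error).
#' @export
map_concept_to_nhs <- function(cb, concept_code) {
  stopifnot(inherits(cb, "codebook"))
  idx <- match(concept_code, cb$concepts$concept_code)
  cb$concepts$nhs_category[idx]
}

#' Aggregate NHS letters to high-level groups under a dialect
#'
#' @param cb A `codebook`.
#' @param letter Character vector over the 19 letters, `X`, `"99"` or the
#'   `WHITE_UNSPECIFIED` sentinel.
#' @param dialect_name One of `"SDE"`, `"CENSUS_2011"`, `"CENSUS_2021"`.
#' @return Character vector of high-level group names.
#' @export
map_nhs_to_high_level <- function(cb, letter, dialect_name = "SDE") {
  stopifnot(inherits(cb, "codebook"))
  check_dialect(cb, dialect_name)
  map <- cb$dialects[[dialect_name]]
  unknown <- setdiff(unique(letter[!is.na(letter)]), names(map))
  if (length(unknown) > 0) {
    stop("unknown NHS letter(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  unname(map[letter])
}

#' Translate a legacy numeric ethnicity code to its NHS equivalent
#'
#' Legacy numerals 1-9 identify a single letter; `0` meant "White" without
#' distinguishing British/Irish/other, so it translates to the
#' `WHITE_UNSPECIFIED` sentinel, which aggregates to the high-level White
#' group.
#'
#' @param cb A `codebook`.
#' @param numeral Character or integer vector over 0-9.
#' @return Character vector of NHS letters / `WHITE_UNSPECIFIED`.
#' @export
translate_legacy <- function(cb, numeral) {
  stopifnot(inherits(cb, "codebook"))
  numeral <- as.character(numeral)
  bad <- setdiff(unique(numeral[!is.na(numeral)]), cb$legacy$numeral)
  if (length(bad) > 0) {
    stop("invalid legacy numeral(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  cb$legacy$nhs_equivalent[match(numeral, cb$legacy$numeral)]
}

#' Letters whose high-level assignment differs between two dialects
#'
#' @param cb A `codebook`.
#' @param dialect_a,dialect_b Dialect names.
#' @return Character vector of letters (possibly empty).
#' @export
list_dialect_discrepancies <- function(cb, dialect_a, dialect_b) {
  stopifnot(inherits(cb, "codebook"))
  check_dialect(cb, dialect_a)
  check_dialect(cb, dialect_b)
  sort(dialect_diff_letters(cb, dialect_a, dialect_b))
}

#' Default descriptor keyword lists
#'
#' Keyword lists used to classify what a concept label describes: an
#' ethnicity/race term, a religion, a geographical region, and/or a language.
#' These lists are a configurable convention shipped with the package, not a
#' canonical standard; callers with their own terminology conventions should
#' supply their own lists.
#'
#' @return Named list of lowercase keyword vectors, one per descriptor flag.
#' @export
default_descriptor_keywords <- function() {
  list(
    ETHNICITY_RACE = c(
      "white", "black", "asian", "mixed", "race", "ethnic", "arab",
      "traveller", "gypsy", "roma", "hispanic", "latin american", "oriental",
      "caucasian", "afro"
    ),
    RELIGION = c(
      "orthodox", "muslim", "jewish", "jew", "sikh", "hindu", "christian",
      "buddhist", "catholic", "protestant"
    ),
    GEOGRAPHY = c(
      "british", "english", "irish", "scottish", "welsh", "indian",
      "pakistani", "bangladeshi", "chinese", "african", "caribbean",
      "greek", "turkish", "cypriot", "polish", "italian", "portuguese",
      "filipino", "vietnamese", "japanese", "korean", "nepali", "sri lankan",
      "east african", "north african", "european", "american", "kosovan",
      "albanian", "bosnian", "croatian", "serbian", "iranian", "iraqi",
      "kurdish", "somali", "nigerian", "ghanaian", "moroccan", "egyptian",
      "brazilian", "colombian", "malaysian", "thai", "west indian"
    ),
    LANGUAGE = c(
      "speaks", "speaker", "speaking", "language", "bilingual", "gaelic",
      "punjabi", "urdu", "bengali", "gujarati", "hindi", "cantonese",
      "mandarin", "tamil", "arabic speaking"
    )
  )
}

#' Classify a concept label into descriptor flags
#'
#' Case-insensitive whole-word keyword matching of a free-text concept label
#' against per-flag keyword lists. Flags are independent: a label such as
#' "Greek Orthodox" can carry both `GEOGRAPHY` and `RELIGION`.
#'
#' @param label Character vector of non-empty concept labels.
#' @param keyword_config Named list of keyword vectors as produced by
#'   [default_descriptor_keywords()].
#' @return For a single label, a character vector of flags; for several, a
#'   logical matrix with one row per label and one column per flag.
#' @export
classify_concept_descriptors <- function(label,
                                         keyword_config =
                                           default_descriptor_keywords()) {
  if (length(label) == 0 || any(is.na(label)) || any(!nzchar(label))) {
    stop("labels must be non-empty", call. = FALSE)
  }
  flags <- descriptor_flag_names()
  missing_f <- setdiff(flags, names(keyword_config))
  if (length(missing_f) > 0) {
    stop("keyword_config missing flag(s): ",
         paste(missing_f, collapse = ", "), call. = FALSE)
  }
  lab <- tolower(label)
  hit <- vapply(flags, function(f) {
    kws <- keyword_config[[f]]
    if (length(kws) == 0) return(rep(FALSE, length(lab)))
    pat <- paste0("\\b(", paste(gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", kws),
                                collapse = "|"), ")\\b")
    grepl(pat, lab, perl = TRUE)
  }, logical(length(lab)))
  if (length(lab) == 1) {
    flags[as.logical(hit)]
  } else {
    hit <- matrix(hit, nrow = length(lab), dimnames = list(NULL, flags))
    hit
  }
}
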