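# Readers for the pipeline's CSV interfaces. Each validates the header and
# names the missing column on schema mismatch.

require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop(what, " is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  invisible(df)
}

# check the header before applying a typed column spec, so a schema mismatch
# raises one clear error naming the column
check_header <- function(path, cols, what) {
  header <- readr::read_csv(path, n_max = 0,
                            col_types = readr::cols(.default = "c"),
                            progress = FALSE)
  require_columns(header, cols, what)
}

#' Read a person table
#'
#' @param path CSV path with at least `person_id`, `age`, `sex`.
#' @return A tibble.
#' @export
read_persons <- function(path) {
  check_header(path, c("person_id", "age", "sex"), "person table")
  readr::read_csv(path, col_types = readr::cols(
    person_id = "c", age = "i", sex = "c", .default = "?"),
    progress = FALSE)
}

#' Read a primary-care (GDPPR-like) ethnicity record table
#'
#' @param path CSV path with `person_id`, `coding_system`, `code`,
#'   `record_date`.
#' @return A tibble.
#' @export
read_gdppr_records <- function(path) {
  check_header(path, c("person_id", "coding_system", "code", "record_date"),
               "GDPPR record table")
  df <- readr::read_csv(path, col_types = readr::cols(
    person_id = "c", coding_system = "c", code = "c", record_date = "D"),
    progress = FALSE)
  bad <- setdiff(unique(df$coding_system), c("SNOMED", "NHS"))
  if (length(bad) > 0) {
    stop("GDPPR record table has unknown coding_system value(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  df
}

#' Read a hospital (HES-like) ethnicity record table
#'
#' @param path CSV path with `person_id`, `code`, `record_date`.
#' @return A tibble.
#' @export
read_hes_records <- function(path) {
  check_header(path, c("person_id", "code", "record_date"),
               "HES record table")
  readr::read_csv(path, col_types = readr::cols(
    person_id = "c", code = "c", record_date = "D"), progress = FALSE)
}

#' Read a resolved-ethnicity table written by [cmd_harmonise()]
#'
#' @param path CSV path.
#' @return A tibble.
#' @export
read_resolved <- function(path) {
  check_header(path, c("person_id", "concept_code", "nhs_letter",
                       "high_level", "provenance", "had_conflict",
                       "n_distinct_informative_codes"),
               "resolved table")
  readr::read_csv(path, col_types = readr::cols(
    person_id = "c", concept_code = "c", nhs_letter = "c",
    high_level = "c", provenance = "c", had_conflict = "l",
    n_distinct_informative_codes = "i", had_any_record = "l"),
    progress = FALSE)
}
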