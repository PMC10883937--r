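# Shared fixtures and independent oracle implementations used by the
# property-style tests. The oracles are deliberately written as plain,
# explicit loops so they share no code path with the package internals.

fixture_codebook_path <- function() {
  system.file("extdata", "codebook_synthetic.csv", package = "ethnocurate")
}

fixture_codebook <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- load_codebook(fixture_codebook_path())
    cache
  }
})

demo_path <- function(file) {
  system.file("extdata", "demo", file, package = "ethnocurate")
}

empty_gdppr <- function() {
  tibble::tibble(person_id = character(), coding_system = character(),
                 code = character(), record_date = as.Date(character()))
}

empty_hes <- function() {
  tibble::tibble(person_id = character(), code = character(),
                 record_date = as.Date(character()))
}

gdppr_rec <- function(person_id, coding_system, code, date) {
  tibble::tibble(person_id = person_id, coding_system = coding_system,
                 code = code, record_date = as.Date(date))
}

hes_rec <- function(person_id, code, date) {
  tibble::tibble(person_id = person_id, code = code,
                 record_date = as.Date(date))
}

persons_row <- function(person_id, age = 40L, sex = "F") {
  tibble::tibble(person_id = person_id, age = as.integer(age), sex = sex)
}

# ---------------------------------------------------------------------------
# Independent decision-tree oracle.
#
# Records are given as a plain data.frame with columns:
#   stream: "G_SNOMED", "G_NHS" or "HES"
#   code:   concept code / NHS letter / legacy numeral
#   date:   Date
# Resolution is re-derived with explicit loops over the stages and records.
oracle_resolve <- function(recs, cb, dialect = "SDE",
                           strategy = "MOST_RECENT",
                           hes_fallback = TRUE, z_blocks_fallback = FALSE) {
  concept_map <- stats::setNames(cb$concepts$nhs_category,
                                 cb$concepts$concept_code)
  legacy_map <- stats::setNames(cb$legacy$nhs_equivalent, cb$legacy$numeral)
  dialect_map <- cb$dialects[[dialect]]
  letter_of <- function(stream, code) {
    if (stream == "G_SNOMED") {
      if (code %in% names(concept_map)) concept_map[[code]] else NA_character_
    } else if (code %in% names(legacy_map)) {
      legacy_map[[code]]
    } else if (code %in% names(dialect_map)) {
      code
    } else {
      NA_character_
    }
  }
  is_informative <- function(l) !is.na(l) && !(l %in% c("Z", "X", "99"))

  n <- nrow(recs)
  letters <- character(n)
  for (i in seq_len(n)) letters[i] <- letter_of(recs$stream[i], recs$code[i])
  informative <- vapply(seq_len(n), function(i) is_informative(letters[i]),
                        logical(1))

  gdppr_idx <- which(recs$stream %in% c("G_SNOMED", "G_NHS"))
  gdppr_only_z <- length(gdppr_idx) > 0 &&
    any(letters[gdppr_idx] %in% "Z") && !any(informative[gdppr_idx])

  stage_of <- c(G_SNOMED = 1L, G_NHS = 2L, HES = 3L)
  max_stage <- 3L
  if (!hes_fallback) max_stage <- 2L
  if (z_blocks_fallback && gdppr_only_z) max_stage <- 2L

  pick <- NULL
  stage_used <- NA_integer_
  for (k in seq_len(max_stage)) {
    idx <- which(stage_of[recs$stream] == k & informative)
    if (length(idx) == 0) next
    if (strategy == "MOST_RECENT") {
      best <- idx[1]
      for (i in idx[-1]) {
        if (recs$date[i] > recs$date[best]) {
          best <- i
        } else if (recs$date[i] == recs$date[best] &&
                   recs$code[i] < recs$code[best]) {
          # within one stage all records share a coding system, so the date
          # tie-break reduces to the smaller code
          best <- i
        }
      }
      pick <- best
    } else {
      counts <- table(letters[idx])
      modal <- names(counts)[counts == max(counts)]
      if (length(modal) > 1) {
        latest <- sapply(modal, function(l) {
          max(as.numeric(recs$date[idx][letters[idx] == l]))
        })
        modal <- modal[order(-latest, modal)][1]
      }
      cand <- idx[letters[idx] == modal]
      best <- cand[1]
      for (i in cand[-1]) {
        if (recs$date[i] > recs$date[best] ||
            (recs$date[i] == recs$date[best] &&
             recs$code[i] < recs$code[best])) {
          best <- i
        }
      }
      pick <- best
    }
    stage_used <- k
    break
  }

  n_inf <- length(unique(letters[informative]))
  if (is.null(pick)) {
    return(list(nhs_letter = NA_character_, high_level = "Unknown",
                provenance = "NONE", n_informative = n_inf))
  }
  list(
    nhs_letter = letters[pick],
    high_level = unname(dialect_map[[letters[pick]]]),
    provenance = c("GDPPR_SNOMED", "GDPPR_NHS", "HES")[stage_used],
    n_informative = n_inf
  )
}

# Convert an oracle-style record frame into the package's two input tables.
split_streams <- function(recs, person_id = "p1") {
  g <- recs[recs$stream %in% c("G_SNOMED", "G_NHS"), , drop = FALSE]
  h <- recs[recs$stream == "HES", , drop = FALSE]
  list(
    gdppr = tibble::tibble(
      person_id = person_id,
      coding_system = ifelse(g$stream == "G_SNOMED", "SNOMED", "NHS"),
      code = g$code, record_date = g$date),
    hes = tibble::tibble(person_id = person_id, code = h$code,
                         record_date = h$date)
  )
}

# Record templates for the exhaustive decision-tree comparison: six codes
# spanning all three streams (two concepts, two letters incl. Z, a hospital
# letter and a legacy numeral), each at two dates.
oracle_record_pool <- function() {
  codes <- data.frame(
    stream = c("G_SNOMED", "G_SNOMED", "G_NHS", "G_NHS", "HES", "HES"),
    code = c("100000081", "100000111", "A", "Z", "M", "4"),
    stringsAsFactors = FALSE
  )
  dates <- as.Date(c("2019-06-01", "2021-02-15"))
  pool <- codes[rep(seq_len(nrow(codes)), each = length(dates)), ]
  pool$date <- rep(dates, times = nrow(codes))
  rownames(pool) <- NULL
  pool
}

# All multisets of pool rows with size <= max_n (indices, combinations with
# repetition).
multisets_upto <- function(n_items, max_n) {
  out <- list(integer(0))
  for (k in seq_len(max_n)) {
    cmb <- utils::combn(n_items + k - 1, k)
    # map combinations of distinct values to multisets
    sets <- apply(cmb, 2, function(v) v - seq_len(k) + 1L, simplify = FALSE)
    out <- c(out, sets)
  }
  out
}

# Random cohort over the fixture codebook, independent of the package's
# generator: plain sampling of letters/concepts per person.
random_cohort <- function(n_persons, cb, seed, p_z = 0.15,
                          max_records = 4L) {
  set.seed(seed)
  ids <- sprintf("R%04d", seq_len(n_persons))
  g_rows <- list()
  h_rows <- list()
  concept_pool <- cb$concepts$concept_code
  letter_pool <- nhs_letters()
  for (i in seq_len(n_persons)) {
    kg <- sample(0:max_records, 1)
    if (kg > 0) {
      snomed <- runif(kg) < 0.6
      code <- character(kg)
      code[snomed] <- sample(concept_pool, sum(snomed), replace = TRUE)
      code[!snomed] <- sample(letter_pool, sum(!snomed), replace = TRUE,
                              prob = ifelse(letter_pool == "Z", p_z * 10, 1))
      g_rows[[i]] <- tibble::tibble(
        person_id = ids[i],
        coding_system = ifelse(snomed, "SNOMED", "NHS"),
        code = code,
        record_date = as.Date("2015-01-01") + sample(0:2500, kg,
                                                     replace = TRUE))
    }
    kh <- sample(0:max_records, 1)
    if (kh > 0) {
      h_rows[[i]] <- tibble::tibble(
        person_id = ids[i],
        code = sample(c(setdiff(letter_pool, c("T", "W")), as.character(0:9)),
                      kh, replace = TRUE),
        record_date = as.Date("2015-01-01") + sample(0:2500, kh,
                                                     replace = TRUE))
    }
  }
  list(
    persons = tibble::tibble(person_id = ids,
                             age = sample(0:99, n_persons, replace = TRUE),
                             sex = sample(c("F", "M"), n_persons,
                                          replace = TRUE)),
    gdppr = if (length(g_rows)) dplyr::bind_rows(g_rows) else empty_gdppr(),
    hes = if (length(h_rows)) dplyr::bind_rows(h_rows) else empty_hes()
  )
}

# Brute-force per-person pair enumeration for the pair-count conservation
# property: returns total pair mass computed by double loop.
oracle_pair_total <- function(records_letters_by_person) {
  total <- 0L
  for (ls in records_letters_by_person) {
    u <- unique(ls)
    k <- length(u)
    if (k >= 2) {
      for (a in seq_len(k - 1)) {
        for (b in (a + 1):k) total <- total + 1L
      }
    }
  }
  total
}
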