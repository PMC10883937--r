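#' Configuration for the synthetic cohort generator
#'
#' Bundles every knob of the synthetic population, codebook and record
#' generator. Defaults emulate the structure of England-wide linked primary
#' care (GDPPR-like) and hospital (HES-like) ethnicity records: a six-group
#' high-level mixture dominated by White, roughly one person in six with no
#' primary-care ethnicity record (of whom about two thirds can be rescued
#' from hospital records), per-person record multiplicity with occasional
#' conflicting codes, "not stated" (Z) codes, and a concept codebook of
#' several hundred codes of which only about half are ever used.
#'
#' @param n_persons Number of persons to simulate.
#' @param high_level_mixture Named proportions over the six high-level groups
#'   (renormalised to sum to 1). Defaults to the recorded-group distribution
#'   of the England primary-care population: White 77.3%, Asian/Asian British
#'   9.8%, Black/African/Caribbean/Black British 3.6%, Other Ethnic Groups
#'   3.6%, Mixed 2.2%, Unknown 3.2%.
#' @param p_missing_gdppr Probability a person has no primary-care ethnicity
#'   record (default 0.167, the observed one-in-six).
#' @param p_hes_rescue Probability a primary-care-missing person has a
#'   hospital ethnicity record (default 0.635, which takes overall
#'   missingness from 16.7% down to about 6.1%).
#' @param p_not_stated Probability any generated primary-care record is
#'   replaced by a "not stated" (Z) code.
#' @param conflict_rate Probability a person with at least one record in a
#'   stream carries an extra, different code in that stream.
#' @param records_per_person Distribution spec for the per-person record
#'   count: `list(name = "geometric", mean = m)` or
#'   `list(name = "fixed", n = k)`.
#' @param date_range Two calendar dates (coercible by `as.Date`) bounding all
#'   record dates.
#' @param n_concepts Number of concept codes in the generated codebook
#'   (default 489; must be at least 19 so every letter is covered).
#' @param n_concepts_used_target Expected number of distinct concepts that
#'   ever appear in generated records (default 255): concepts are marked
#'   "in circulation" with probability
#'   `n_concepts_used_target / n_concepts` and records draw only from those.
#' @param p_gdppr_nhs_coded Fraction of primary-care records carrying an NHS
#'   letter directly rather than a terminology concept.
#' @param p_hes_coverage Probability a person who has primary-care records
#'   also has hospital records.
#' @param hes_legacy_rate Probability a hospital record uses a pre-2001
#'   legacy numeral instead of a letter (where one exists for the letter).
#' @param p_invalid_age,p_missing_sex Rates of deliberately invalid ages
#'   (< 0 or >= 115) and missing sex, to exercise the eligibility filter.
#' @param missingness_beta_male,missingness_beta_young Log-odds shifts making
#'   primary-care missingness more likely for males and for ages 18-29 (the
#'   pattern seen in the real data, where 58.6% of the missing group were
#'   male and ages 18-29 had the most missingness). The intercept is
#'   calibrated so the marginal missingness equals `p_missing_gdppr`.
#' @param seed Integer seed; per-table substreams use fixed offsets
#'   (codebook +1, population +2, records +3).
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_persons = 10000,
                             high_level_mixture = c(
                               "White" = 0.773,
                               "Asian/Asian British" = 0.098,
                               "Black/African/Caribbean/Black British" = 0.036,
                               "Other Ethnic Groups" = 0.036,
                               "Mixed" = 0.022,
                               "Unknown" = 0.032),
                             p_missing_gdppr = 0.167,
                             p_hes_rescue = 0.635,
                             p_not_stated = 0.05,
                             conflict_rate = 0.12,
                             records_per_person = list(name = "geometric",
                                                       mean = 2),
                             date_range = c("1997-01-01", "2022-04-23"),
                             n_concepts = 489,
                             n_concepts_used_target = 255,
                             p_gdppr_nhs_coded = 0.2,
                             p_hes_coverage = 0.4,
                             hes_legacy_rate = 0.02,
                             p_invalid_age = 0.002,
                             p_missing_sex = 0.002,
                             missingness_beta_male = 0.4,
                             missingness_beta_young = 0.5,
                             seed = 1L) {
  stopifnot(length(n_persons) == 1, n_persons >= 0)
  probs <- c(p_missing_gdppr = p_missing_gdppr, p_hes_rescue = p_hes_rescue,
             p_not_stated = p_not_stated, conflict_rate = conflict_rate,
             p_gdppr_nhs_coded = p_gdppr_nhs_coded,
             p_hes_coverage = p_hes_coverage,
             hes_legacy_rate = hes_legacy_rate,
             p_invalid_age = p_invalid_age, p_missing_sex = p_missing_sex)
  if (any(probs < 0 | probs > 1)) {
    stop("probabilities must lie in [0, 1]: ",
         paste(names(probs)[probs < 0 | probs > 1], collapse = ", "),
         call. = FALSE)
  }
  bad_groups <- setdiff(names(high_level_mixture), high_level_groups())
  if (length(bad_groups) > 0) {
    stop("unknown high-level group(s) in mixture: ",
         paste(bad_groups, collapse = ", "), call. = FALSE)
  }
  if (any(high_level_mixture < 0) || sum(high_level_mixture) <= 0) {
    stop("mixture proportions must be non-negative and sum > 0",
         call. = FALSE)
  }
  if (n_concepts < 19) {
    stop("n_concepts must be >= 19 (one per NHS letter)", call. = FALSE)
  }
  if (!records_per_person$name %in% c("geometric", "fixed")) {
    stop("records_per_person$name must be 'geometric' or 'fixed'",
         call. = FALSE)
  }
  mixture <- high_level_mixture / sum(high_level_mixture)
  # fill unmentioned groups with 0 so downstream indexing is total
  full <- stats::setNames(rep(0, 6), high_level_groups())
  full[names(mixture)] <- mixture
  structure(
    list(n_persons = as.integer(n_persons), high_level_mixture = full,
         p_missing_gdppr = p_missing_gdppr, p_hes_rescue = p_hes_rescue,
         p_not_stated = p_not_stated, conflict_rate = conflict_rate,
         records_per_person = records_per_person,
         date_range = as.Date(date_range),
         n_concepts = as.integer(n_concepts),
         n_concepts_used_target = as.integer(n_concepts_used_target),
         p_gdppr_nhs_coded = p_gdppr_nhs_coded,
         p_hes_coverage = p_hes_coverage,
         hes_legacy_rate = hes_legacy_rate,
         p_invalid_age = p_invalid_age, p_missing_sex = p_missing_sex,
         missingness_beta_male = missingness_beta_male,
         missingness_beta_young = missingness_beta_young,
         seed = as.integer(seed)),
    class = "synthetic_config"
  )
}

# Letters available within each high-level group under the SDE dialect
# (ground truth is defined under SDE), with plausible within-group weights.
letters_within_group <- function() {
  list(
    "White" = c(A = 0.80, C = 0.15, B = 0.05),
    "Mixed" = c(D = 0.30, F = 0.25, G = 0.25, E = 0.20),
    "Asian/Asian British" = c(H = 0.38, J = 0.29, K = 0.12, L = 0.21),
    "Black/African/Caribbean/Black British" = c(N = 0.55, M = 0.25, P = 0.20),
    "Other Ethnic Groups" = c(S = 0.50, R = 0.35, W = 0.10, T = 0.05),
    "Unknown" = c(Z = 1)
  )
}

# Per-letter fragment pools used to compose concept labels so that the
# descriptor classifier sees realistic text (geography terms, ethnicity/race
# terms, religions, language phrases).
letter_label_pools <- function() {
  list(
    A = list(geo = c("British", "English", "Scottish", "Welsh"),
             eth = c("White")),
    B = list(geo = c("Irish"), eth = c("White")),
    C = list(geo = c("Polish", "Greek", "Italian", "Portuguese", "Albanian",
                     "Bosnian", "Croatian", "Serbian", "Kosovan",
                     "Greek Cypriot"),
             eth = c("White", "Other White")),
    T = list(geo = c("Irish"), eth = c("Gypsy", "Traveller", "Roma")),
    D = list(geo = c("Caribbean"), eth = c("White and Black Caribbean",
                                           "Mixed")),
    E = list(geo = c("African"), eth = c("White and Black African", "Mixed")),
    F = list(geo = c("Indian", "Chinese"), eth = c("White and Asian",
                                                   "Mixed")),
    G = list(geo = c("American"), eth = c("Other Mixed", "Mixed")),
    H = list(geo = c("Indian"), eth = c("Asian", "British Asian"),
             lang = c("Punjabi speaking", "Hindi speaking",
                      "Gujarati speaking"),
             rel = c("Hindu", "Sikh")),
    J = list(geo = c("Pakistani"), eth = c("Asian"),
             lang = c("Urdu speaking", "Punjabi speaking"),
             rel = c("Muslim")),
    K = list(geo = c("Bangladeshi"), eth = c("Asian"),
             lang = c("Bengali speaking", "Sylheti speaking")),
    L = list(geo = c("Sri Lankan", "Nepali", "East African", "Filipino",
                     "Malaysian"),
             eth = c("Other Asian", "Asian", "Black East African Asian"),
             lang = c("Tamil speaking")),
    R = list(geo = c("Chinese"), eth = c("Asian"),
             lang = c("Cantonese speaking", "Mandarin speaking")),
    M = list(geo = c("Caribbean", "West Indian"), eth = c("Black")),
    N = list(geo = c("African", "Somali", "Nigerian", "Ghanaian"),
             eth = c("Black")),
    P = list(geo = c("Caribbean"), eth = c("Other Black", "Black British",
                                           "Black")),
    S = list(geo = c("Vietnamese", "Japanese", "Korean", "Thai", "Moroccan",
                     "Egyptian", "Brazilian", "Colombian", "Turkish",
                     "Iranian", "Iraqi"),
             eth = c("Other ethnic group"),
             rel = c("Buddhist", "Muslim", "Jewish")),
    W = list(geo = c("Moroccan", "Egyptian", "Iraqi"), eth = c("Arab"),
             lang = c("Arabic speaking")),
    Z = list(eth = c("Ethnicity not stated", "Not stated",
                     "Ethnicity unknown - not stated",
                     "Declined to state ethnicity"))
  )
}

compose_label <- function(letter, pools) {
  p <- pools[[letter]]
  if (letter == "Z") return(sample(p$eth, 1))
  opts <- c("geo", "eth_geo", if (!is.null(p$lang)) "lang_geo",
            if (!is.null(p$rel)) "rel_geo", "eth")
  w <- c(0.30, 0.40, if (!is.null(p$lang)) 0.15,
         if (!is.null(p$rel)) 0.05, 0.10)
  kind <- sample(opts, 1, prob = w)
  geo <- if (!is.null(p$geo)) sample(p$geo, 1) else sample(p$eth, 1)
  switch(kind,
    geo = geo,
    eth_geo = paste0(sample(p$eth, 1), " - ", geo),
    lang_geo = paste(sample(p$lang, 1), geo),
    rel_geo = paste(geo, sample(p$rel, 1)),
    eth = sample(p$eth, 1)
  )
}

#' Generate a synthetic concept codebook
#'
#' Produces a codebook with `cfg$n_concepts` concept codes distributed over
#' the 19 NHS letters (each letter covered at least once), with free-text
#' labels composed from per-letter fragment pools so that descriptor
#' classification is exercised, and descriptor flags derived from those
#' labels via [classify_concept_descriptors()]. A random subset of concepts
#' of expected size `cfg$n_concepts_used_target` is marked as being "in
#' circulation" (stored in the `active_concepts` attribute); the record
#' generator draws only from that subset, so the remaining concepts exist in
#' the codebook but are never assigned to anyone.
#'
#' @param cfg A [synthetic_config()].
#' @return A `codebook` with an `active_concepts` attribute.
#' @export
generate_codebook <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(cfg$seed + 1L)
  n <- cfg$n_concepts
  pools <- letter_label_pools()
  ltrs <- nhs_letters()
  # every letter once, the remainder weighted towards letters that carry
  # many concepts in real terminologies
  extra_w <- stats::setNames(rep(1, 19), ltrs)
  extra_w[c("A", "C", "L", "S", "N")] <- c(4, 6, 5, 6, 3)
  letter_of <- c(ltrs,
                 if (n > 19) sample(ltrs, n - 19, replace = TRUE,
                                    prob = extra_w[ltrs]))
  codes <- sprintf("%09d", sample.int(999999999L, n))
  labels <- vapply(letter_of, compose_label, character(1), pools = pools)
  flags <- classify_concept_descriptors(labels)
  if (is.null(dim(flags))) flags <- matrix(flags, nrow = 1,
                                           dimnames = list(NULL,
                                                           descriptor_flag_names()))
  concepts <- tibble(
    concept_code = codes,
    label = labels,
    nhs_category = letter_of,
    flag_ethnicity_race = flags[, "ETHNICITY_RACE"],
    flag_religion = flags[, "RELIGION"],
    flag_geography = flags[, "GEOGRAPHY"],
    flag_language = flags[, "LANGUAGE"]
  )
  cb <- new_codebook(concepts)
  p_active <- min(1, cfg$n_concepts_used_target / n)
  active <- codes[stats::runif(n) < p_active]
  # keep at least one concept per letter in circulation
  first_per_letter <- codes[match(ltrs, letter_of)]
  active <- union(active, first_per_letter)
  attr(cb, "active_concepts") <- active
  cb
}

#' Generate a synthetic person table
#'
#' Draws `cfg$n_persons` persons with demographics shaped like an
#' England-wide primary-care register: ages roughly normal around the
#' low forties, an even sex split, nine England regions, deprivation
#' deciles, thirteen comorbidity flags at register-level prevalences, and a
#' ground-truth high-level ethnicity drawn from `cfg$high_level_mixture`. A
#' small configurable fraction of rows carries an invalid age or missing sex
#' to exercise the eligibility filter.
#'
#' @param cfg A [synthetic_config()].
#' @return A tibble with one row per person, including the latent
#'   `true_high_level` column.
#' @export
generate_population <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(cfg$seed + 2L)
  n <- cfg$n_persons
  if (n == 0) {
    return(tibble(person_id = character(), age = integer(),
                  sex = character(), region = character(),
                  imd_decile = integer(), died = logical(),
                  true_high_level = character()))
  }
  regions <- c("London", "North East", "North West",
               "Yorkshire and The Humber", "East Midlands", "West Midlands",
               "South East", "East of England", "South West")
  region_w <- c(0.152, 0.035, 0.119, 0.090, 0.065, 0.095, 0.137, 0.086,
                0.074)
  comorbidity <- c(atrial_fibrillation = 0.024, acute_mi = 0.016,
                   chronic_kidney_disease = 0.040, copd = 0.020,
                   heart_failure = 0.013, pulmonary_embolism = 0.0001,
                   cancer = 0.114, dementia = 0.010, diabetes = 0.067,
                   hypertension = 0.144, liver_disease = 0.003,
                   obesity = 0.048, stroke = 0.020)

  age <- as.integer(pmax(0, pmin(114, round(stats::rnorm(n, 42, 24)))))
  invalid <- stats::runif(n) < cfg$p_invalid_age
  age[invalid] <- sample(c(-1L, -5L, 115L, 120L, 127L), sum(invalid),
                         replace = TRUE)
  sex <- sample(c("F", "M"), n, replace = TRUE)
  sex[stats::runif(n) < cfg$p_missing_sex] <- NA_character_
  region <- sample(regions, n, replace = TRUE, prob = region_w)
  region[stats::runif(n) < 0.10] <- NA_character_
  imd <- sample.int(10L, n, replace = TRUE)
  imd[stats::runif(n) < 0.09] <- NA_integer_

  out <- tibble(
    person_id = sprintf("P%07d", seq_len(n)),
    age = age, sex = sex, region = region, imd_decile = imd
  )
  for (cm in names(comorbidity)) {
    out[[paste0("cm_", cm)]] <- stats::runif(n) < comorbidity[[cm]]
  }
  out$died <- stats::runif(n) < 0.021
  out$true_high_level <- sample(high_level_groups(), n, replace = TRUE,
                                prob = cfg$high_level_mixture)
  out
}

# Calibrated logistic missingness: linear predictor from sex/age shifts,
# intercept solved so mean propensity equals the target marginal rate.
missingness_propensity <- function(persons, cfg) {
  p <- cfg$p_missing_gdppr
  if (p <= 0) return(rep(0, nrow(persons)))
  if (p >= 1) return(rep(1, nrow(persons)))
  lin <- cfg$missingness_beta_male *
    (!is.na(persons$sex) & persons$sex == "M") +
    cfg$missingness_beta_young *
    (!is.na(persons$age) & persons$age >= 18 & persons$age <= 29)
  f <- function(delta) mean(stats::plogis(lin + delta)) - p
  delta <- stats::uniroot(f, c(-30, 30))$root
  stats::plogis(lin + delta)
}

draw_record_counts <- function(spec, n) {
  if (n == 0) return(integer())
  switch(spec$name,
    geometric = stats::rgeom(n, prob = 1 / spec$mean) + 1L,
    fixed = rep(as.integer(spec$n), n)
  )
}

sample_dates <- function(n, range) {
  days <- as.integer(range[2] - range[1])
  range[1] + sample.int(days + 1L, n, replace = TRUE) - 1L
}

# Conflict partner palette reflecting the frequently co-occurring code pairs
# in national records: A-C, A-Z, C-S most common; L-S, N-P, H-L among
# minority codes.
conflict_partner <- function(letters) {
  palette <- list(
    A = c(C = 0.6, Z = 0.4), C = c(A = 0.6, S = 0.4), S = c(C = 0.5,
                                                            L = 0.5),
    L = c(S = 0.6, H = 0.4), N = c(P = 1), P = c(N = 1), H = c(L = 1),
    B = c(A = 1), Z = c(A = 1)
  )
  informative <- nhs_letters(informative_only = TRUE)
  vapply(letters, function(l) {
    if (!is.null(palette[[l]])) {
      sample(names(palette[[l]]), 1, prob = palette[[l]])
    } else {
      sample(setdiff(informative, l), 1)
    }
  }, character(1), USE.NAMES = FALSE)
}

#' Generate synthetic primary-care and hospital ethnicity records
#'
#' Each person not selected as primary-care-missing receives one or more
#' dated GDPPR-like records coded as terminology concepts (or, for a
#' configurable fraction, NHS letters) consistent with their ground-truth
#' group; persons with no primary-care record may be "rescued" by
#' HES-like hospital records, which carry NHS letters only (never `T` or
#' `W`, which the 2001-census-based hospital table lacks; those letters are
#' substituted by `S`, preserving the high-level group) and occasionally a
#' pre-2001 legacy numeral. Conflicting extra codes are injected at
#' `cfg$conflict_rate`, preferentially drawn from the code pairs most often
#' seen co-occurring in national records; any record may be replaced by a
#' "not stated" (Z) code at `cfg$p_not_stated`.
#'
#' @param persons Person table from [generate_population()].
#' @param cb Codebook from [generate_codebook()] (its `active_concepts`
#'   attribute restricts which concepts circulate).
#' @param cfg A [synthetic_config()].
#' @return A list with tibbles `gdppr` (`person_id`, `coding_system`,
#'   `code`, `record_date`) and `hes` (`person_id`, `code`, `record_date`).
#' @export
generate_records <- function(persons, cb, cfg) {
  stopifnot(inherits(cfg, "synthetic_config"), inherits(cb, "codebook"))
  if (nrow(cb$concepts) == 0) {
    stop("codebook has no concepts; cannot generate concept-coded records",
         call. = FALSE)
  }
  set.seed(cfg$seed + 3L)
  empty_g <- tibble(person_id = character(), coding_system = character(),
                    code = character(), record_date = as.Date(character()))
  empty_h <- tibble(person_id = character(), code = character(),
                    record_date = as.Date(character()))
  if (nrow(persons) == 0) return(list(gdppr = empty_g, hes = empty_h))

  active <- attr(cb, "active_concepts")
  if (is.null(active)) active <- cb$concepts$concept_code
  pool <- cb$concepts[cb$concepts$concept_code %in% active, ]
  concepts_by_letter <- split(pool$concept_code, pool$nhs_category)

  lw <- letters_within_group()
  home_letter <- vapply(persons$true_high_level, function(g) {
    w <- lw[[g]]
    if (length(w) == 1) names(w) else sample(names(w), 1, prob = w)
  }, character(1), USE.NAMES = FALSE)

  gdppr_missing <- stats::runif(nrow(persons)) <
    missingness_propensity(persons, cfg)

  draw_concepts <- function(letters) {
    out <- character(length(letters))
    for (l in unique(letters)) {
      idx <- which(letters == l)
      cands <- concepts_by_letter[[l]]
      if (is.null(cands)) cands <- pool$concept_code
      out[idx] <- if (length(cands) == 1) {
        rep(cands, length(idx))
      } else {
        sample(cands, length(idx), replace = TRUE)
      }
    }
    out
  }

  make_gdppr <- function(pid, letters) {
    if (length(pid) == 0) return(empty_g)
    n <- length(pid)
    # not-stated replacement, then coding system, then code draw
    letters[stats::runif(n) < cfg$p_not_stated] <- "Z"
    snomed <- stats::runif(n) >= cfg$p_gdppr_nhs_coded
    code <- character(n)
    code[snomed] <- draw_concepts(letters[snomed])
    code[!snomed] <- letters[!snomed]
    tibble(person_id = pid,
           coding_system = ifelse(snomed, "SNOMED", "NHS"),
           code = code,
           record_date = sample_dates(n, cfg$date_range))
  }

  has_gdppr <- !gdppr_missing
  k_g <- draw_record_counts(cfg$records_per_person, sum(has_gdppr))
  base_pid <- rep(persons$person_id[has_gdppr], k_g)
  base_letter <- rep(home_letter[has_gdppr], k_g)
  gdppr <- make_gdppr(base_pid, base_letter)

  # conflicting extra code for a subset of persons with >= 1 GDPPR record
  conf_sel <- has_gdppr & stats::runif(nrow(persons)) < cfg$conflict_rate
  if (any(conf_sel)) {
    partner <- conflict_partner(home_letter[conf_sel])
    gdppr <- dplyr::bind_rows(
      gdppr, make_gdppr(persons$person_id[conf_sel], partner))
  }
  gdppr <- dplyr::arrange(gdppr, .data$person_id, .data$record_date,
                          .data$code)

  # Hospital records: letters only, T/W replaced by S, optional legacy
  # numerals where an equivalent exists.
  hes_letter_of <- function(l) ifelse(l %in% c("T", "W"), "S", l)
  legacy_numeral <- stats::setNames(default_legacy_map()$numeral,
                                    default_legacy_map()$nhs_equivalent)
  make_hes <- function(pid, letters) {
    if (length(pid) == 0) return(empty_h)
    n <- length(pid)
    letters[stats::runif(n) < cfg$p_not_stated] <- "Z"
    letters <- hes_letter_of(letters)
    code <- letters
    # A/B/C share legacy numeral 0 ("White" unspecified)
    leg <- ifelse(letters %in% c("A", "B", "C"), "0",
                  unname(legacy_numeral[letters]))
    use_leg <- !is.na(leg) & stats::runif(n) < cfg$hes_legacy_rate
    code[use_leg] <- leg[use_leg]
    tibble(person_id = pid, code = code,
           record_date = sample_dates(n, cfg$date_range))
  }

  has_hes <- ifelse(gdppr_missing,
                    stats::runif(nrow(persons)) < cfg$p_hes_rescue,
                    stats::runif(nrow(persons)) < cfg$p_hes_coverage)
  k_h <- draw_record_counts(cfg$records_per_person, sum(has_hes))
  hes <- make_hes(rep(persons$person_id[has_hes], k_h),
                  rep(home_letter[has_hes], k_h))
  conf_h <- has_hes & stats::runif(nrow(persons)) < cfg$conflict_rate
  if (any(conf_h)) {
    partner_h <- conflict_partner(home_letter[conf_h])
    hes <- dplyr::bind_rows(
      hes, make_hes(persons$person_id[conf_h], partner_h))
  }
  hes <- dplyr::arrange(hes, .data$person_id, .data$record_date, .data$code)

  list(gdppr = gdppr, hes = hes)
}
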