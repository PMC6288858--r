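# Synthetic HDSS world: population registry, corrupted encounter records,
# and a proportional-hazards time-to-care-registration outcome with known
# gold-standard links.

ENC_SOURCES <- c("sero_survey", "HTC", "ANC")
AGE_LEVELS <- c("15-29", "30-39", "40-49", "50+")
RURALITY_LEVELS <- c("rural", "peri_urban", "urban")
DIST_LEVELS <- c("<1", "1-1.9", "2-4.9", "5-11")
MODALITY_LEVELS <- c("sero_survey", "clinic")

# Calendar anchor: day 0 of the simulated study window, expressed as a
# fractional year. All other date arithmetic is in integer days.
EPOCH_YEAR <- 2014.917
STUDY_DAYS <- 1035L

#' Deterministic syllable-built name pool
#'
#' Names are composed from fixed syllable sets so that distinct names share
#' prefixes and near-anagrams, producing Jaro-Winkler similarities in the
#' (0.8, 1.0) range that a linkage comparator must discriminate. The pool is
#' a pure function of `n` and `kind`; no random numbers are consumed.
#'
#' @param n pool size.
#' @param kind `"given"` or `"family"`; the two kinds use different syllable
#'   orders so the pools are disjoint.
#' @return character vector of `n` distinct uppercase names.
#' @export
name_pool <- function(n, kind = c("given", "family")) {
  kind <- match.arg(kind)
  s1 <- c("MA", "KA", "JU", "NE", "SA", "LU", "BA", "MW", "ZA", "TU", "KI", "DO")
  s2 <- c("RA", "LI", "MBO", "SHA", "NI", "KO", "GE", "YA", "TE", "FU")
  s3 <- c("NI", "SA", "KA", "LE", "MBA", "RU", "YO", "")
  if (kind == "family") { tmp <- s1; s1 <- s2; s2 <- tmp }
  g <- expand.grid(a = s1, b = s2, c = s3, stringsAsFactors = FALSE)
  pool <- unique(paste0(g$a, g$b, g$c))
  if (n > length(pool)) {
    stop("name pool '", kind, "' supports at most ", length(pool), " names")
  }
  pool[seq_len(n)]
}

# Zipf-like sampling weights over a pool of size n.
zipf_weights <- function(n, exponent = 1) {
  w <- 1 / seq_len(n)^exponent
  w / sum(w)
}

#' Population registry configuration
#'
#' @param n number of persons in the registry.
#' @param n_villages number of villages.
#' @param subvillages_per_village sub-villages nested in each village.
#' @param household_size_mean mean household size (>= 1).
#' @param households_per_tcl households sharing one ten-cell leader.
#' @param pool_size_given,pool_size_family sizes of the finite name pools;
#'   finite pools force realistic name collisions between distinct people.
#' @param zipf_exponent skew of name frequencies (1 = classic Zipf).
#' @param birth_year_range inclusive range of birth years.
#' @param hdss_completeness named presence probabilities for registry fields
#'   (the registry is nearly complete; encounters are corrupted separately).
#' @return a `population_config` list.
#' @export
population_config <- function(n = 3000,
                              n_villages = 7,
                              subvillages_per_village = 4,
                              household_size_mean = 4.5,
                              households_per_tcl = 10,
                              pool_size_given = 40,
                              pool_size_family = 40,
                              zipf_exponent = 1,
                              birth_year_range = c(1930L, 2012L),
                              hdss_completeness = c(birth_year = 0.994,
                                                    tcl_name = 0.994,
                                                    hh_member_name = 0.999)) {
  cfg <- list(n = as.integer(n), n_villages = as.integer(n_villages),
              subvillages_per_village = as.integer(subvillages_per_village),
              household_size_mean = household_size_mean,
              households_per_tcl = as.integer(households_per_tcl),
              pool_size_given = as.integer(pool_size_given),
              pool_size_family = as.integer(pool_size_family),
              zipf_exponent = zipf_exponent,
              birth_year_range = as.integer(birth_year_range),
              hdss_completeness = hdss_completeness)
  class(cfg) <- "population_config"
  cfg
}

check_population_config <- function(config) {
  if (!is.finite(config$n) || config$n <= 0)
    stop("population_config: 'n' must be a positive integer")
  if (config$n_villages <= 0)
    stop("population_config: 'n_villages' must be positive")
  if (config$household_size_mean < 1)
    stop("population_config: 'household_size_mean' must be >= 1")
  if (config$pool_size_given <= 0 || config$pool_size_family <= 0)
    stop("population_config: name pools must be nonempty")
  invisible(config)
}

#' Generate a synthetic HDSS person registry
#'
#' Builds households nested in sub-villages and villages, assigns each
#' household planar coordinates (km) around a care clinic at the origin,
#' groups households under ten-cell leaders, and draws names from finite
#' Zipf-weighted pools. Identical `(config, seed)` reproduce identical
#' output.
#'
#' @param config a [population_config()].
#' @param seed integer RNG seed.
#' @return an object of class `hdss_registry`: a list with `persons` (one row
#'   per person), `episodes` (residency episodes, half-open day intervals;
#'   `end_day = NA` means open), and the `config`.
#' @export
generate_population <- function(config = population_config(), seed = 1L) {
  check_population_config(config)
  set.seed(seed)
  n <- config$n

  given_pool <- name_pool(config$pool_size_given, "given")
  family_pool <- name_pool(config$pool_size_family, "family")
  wg <- zipf_weights(length(given_pool), config$zipf_exponent)
  wf <- zipf_weights(length(family_pool), config$zipf_exponent)

  # households until the population is covered
  n_hh_guess <- ceiling(n / max(config$household_size_mean - 1, 1))
  hh_sizes <- 1L + stats::rpois(2L * n_hh_guess + 8L,
                                config$household_size_mean - 1)
  cum <- cumsum(hh_sizes)
  n_hh <- which(cum >= n)[1L]
  hh_sizes <- hh_sizes[seq_len(n_hh)]
  hh_sizes[n_hh] <- hh_sizes[n_hh] - (cum[n_hh] - n)
  if (hh_sizes[n_hh] == 0L) { hh_sizes <- hh_sizes[-n_hh]; n_hh <- n_hh - 1L }

  # villages, sub-villages and their attributes
  villages <- sprintf("VILLAGE_%02d", seq_len(config$n_villages))
  sv <- expand.grid(village = villages,
                    sv_i = seq_len(config$subvillages_per_village),
                    stringsAsFactors = FALSE)
  sv$sub_village <- sprintf("%s_SV%d", sv$village, sv$sv_i)
  sv$rurality <- sample(RURALITY_LEVELS, nrow(sv), replace = TRUE,
                        prob = c(0.5, 0.25, 0.25))
  sv$paved_road <- runif(nrow(sv)) < 0.45
  # sub-village centres: distance to the clinic (origin) spans the bands
  r <- runif(nrow(sv), 0.2, 10.5)
  th <- runif(nrow(sv), 0, 2 * pi)
  sv$cx <- r * cos(th)
  sv$cy <- r * sin(th)

  hh_sv <- sample(nrow(sv), n_hh, replace = TRUE)
  hh <- data.frame(household_id = sprintf("H%05d", seq_len(n_hh)),
                   sub_village = sv$sub_village[hh_sv],
                   village = sv$village[hh_sv],
                   rurality = sv$rurality[hh_sv],
                   paved_road = sv$paved_road[hh_sv],
                   x_km = sv$cx[hh_sv] + rnorm(n_hh, 0, 0.4),
                   y_km = sv$cy[hh_sv] + rnorm(n_hh, 0, 0.4),
                   stringsAsFactors = FALSE)
  # ten-cell leader groups within sub-village
  ord <- order(hh_sv)
  tcl_grp <- integer(n_hh)
  tcl_grp[ord] <- ave(seq_along(ord), hh_sv[ord],
                      FUN = function(i) (seq_along(i) - 1L) %/%
                        config$households_per_tcl)
  tcl_key <- paste0(hh$sub_village, "_TCL", tcl_grp + 1L)
  ukey <- unique(tcl_key)
  tcl_names <- data.frame(key = ukey,
                          tcl_name_1 = sample(given_pool, length(ukey),
                                              replace = TRUE, prob = wg),
                          tcl_name_2 = sample(family_pool, length(ukey),
                                              replace = TRUE, prob = wf),
                          stringsAsFactors = FALSE)
  hh$tcl_name_1 <- tcl_names$tcl_name_1[match(tcl_key, tcl_names$key)]
  hh$tcl_name_2 <- tcl_names$tcl_name_2[match(tcl_key, tcl_names$key)]

  # persons
  hh_of_person <- rep(seq_len(n_hh), hh_sizes)
  persons <- hh[hh_of_person, , drop = FALSE]
  rownames(persons) <- NULL
  persons$person_id <- sprintf("P%06d", seq_len(n))
  persons$name_1 <- sample(given_pool, n, replace = TRUE, prob = wg)
  persons$name_2 <- sample(family_pool, n, replace = TRUE, prob = wf)
  persons$sex <- sample(c("F", "M"), n, replace = TRUE)
  byr <- config$birth_year_range
  persons$birth_year <- sample(byr[1]:byr[2], n, replace = TRUE)
  persons$birth_month <- sample(1:12, n, replace = TRUE)
  persons$birth_day <- sample(1:28, n, replace = TRUE)

  # another household member's names as a matching identifier
  idx_in_hh <- sequence(hh_sizes)
  nxt <- ifelse(hh_sizes[hh_of_person] == 1L, NA_integer_,
                cumsum(hh_sizes)[hh_of_person] - hh_sizes[hh_of_person] +
                  (idx_in_hh %% hh_sizes[hh_of_person]) + 1L)
  persons$hh_member_name_1 <- ifelse(is.na(nxt), NA, persons$name_1[nxt])
  persons$hh_member_name_2 <- ifelse(is.na(nxt), NA, persons$name_2[nxt])

  persons$distance_km <- sqrt(persons$x_km^2 + persons$y_km^2)
  persons$distance_band <- cut(pmin(persons$distance_km, 11),
                               breaks = c(-Inf, 1, 2, 5, Inf),
                               labels = DIST_LEVELS, right = FALSE)
  persons$distance_band <- as.character(persons$distance_band)

  # registry-side missingness (the registry is nearly complete)
  comp <- config$hdss_completeness
  persons$birth_year[runif(n) >= comp[["birth_year"]]] <- NA
  miss_tcl <- runif(n) >= comp[["tcl_name"]]
  persons$tcl_name_1[miss_tcl] <- NA
  persons$tcl_name_2[miss_tcl] <- NA
  miss_hh <- runif(n) >= comp[["hh_member_name"]]
  persons$hh_member_name_1[miss_hh] <- NA
  persons$hh_member_name_2[miss_hh] <- NA

  # residency episodes: one open episode, some persons a closed earlier one
  main_start <- -sample(30:3650, n, replace = TRUE)
  episodes <- data.frame(person_id = persons$person_id,
                         start_day = main_start,
                         end_day = NA_integer_,
                         stringsAsFactors = FALSE)
  prev <- runif(n) < 0.2
  if (any(prev)) {
    end2 <- main_start[prev] - sample(30:300, sum(prev), replace = TRUE)
    episodes <- rbind(episodes,
                      data.frame(person_id = persons$person_id[prev],
                                 start_day = end2 - sample(100:2000, sum(prev),
                                                           replace = TRUE),
                                 end_day = end2,
                                 stringsAsFactors = FALSE))
  }
  episodes <- episodes[order(episodes$person_id, episodes$start_day), ]
  rownames(episodes) <- NULL

  first <- c("person_id", "name_1", "name_2", "sex", "birth_year",
             "birth_month", "birth_day", "village", "sub_village",
             "household_id", "tcl_name_1", "tcl_name_2",
             "hh_member_name_1", "hh_member_name_2")
  persons <- persons[, c(first, setdiff(names(persons), first))]

  structure(list(persons = persons, episodes = episodes, config = config),
            class = "hdss_registry")
}

#' @export
print.hdss_registry <- function(x, ...) {
  cat("<hdss_registry> ", nrow(x$persons), " persons, ",
      length(unique(x$persons$household_id)), " households, ",
      length(unique(x$persons$village)), " villages\n", sep = "")
  invisible(x)
}

#' Identifier-corruption configuration
#'
#' Field completeness defaults follow the observed completeness of matching
#' identifiers in the study databases (sero-survey vs pooled clinic sources);
#' the error mechanisms (typos, name-order swaps, birth-year slips) are the
#' generator's own model of how identifiers are "reported with error".
#' Second ten-cell-leader / household-member names are generated nested in
#' the first (present only when the first is), matching how paired name
#' fields co-occur on real forms; marginal presence still equals the
#' configured probability.
#'
#' @param typo_rate probability each recorded name receives one random
#'   character substitution, transposition or deletion.
#' @param name_swap_rate probability the first/second personal names are
#'   recorded in exchanged order.
#' @param birth_year_error_rate probability the recorded birth year is
#'   perturbed; `birth_year_error_sd` scales the (nonzero, integer) shift.
#' @param birth_md_error_rate probability recorded birth month/day is wrong.
#' @param sex_error_rate probability recorded sex is flipped.
#' @param geo_error_rate probability a different sub-village (and its
#'   village) is recorded.
#' @param completeness per-source named lists of field presence
#'   probabilities.
#' @return a `corruption_config` list.
#' @export
corruption_config <- function(typo_rate = 0.25,
                              name_swap_rate = 0.10,
                              birth_year_error_rate = 0.45,
                              birth_year_error_sd = 3,
                              birth_md_error_rate = 0.45,
                              sex_error_rate = 0.02,
                              geo_error_rate = 0.30,
                              completeness = default_completeness()) {
  cfg <- list(typo_rate = typo_rate, name_swap_rate = name_swap_rate,
              birth_year_error_rate = birth_year_error_rate,
              birth_year_error_sd = birth_year_error_sd,
              birth_md_error_rate = birth_md_error_rate,
              sex_error_rate = sex_error_rate,
              geo_error_rate = geo_error_rate,
              completeness = completeness)
  probs <- c(typo_rate, name_swap_rate, birth_year_error_rate,
             birth_md_error_rate, sex_error_rate, geo_error_rate,
             unlist(completeness))
  if (any(probs < 0 | probs > 1))
    stop("corruption_config: all probabilities must be in [0, 1]")
  class(cfg) <- "corruption_config"
  cfg
}

#' Default field-completeness profiles by encounter source
#'
#' Sero-survey and clinic profiles mirror the completeness of matching
#' identifiers reported for the study databases (first/second names, year of
#' birth, sex ~100%; third name 13.3% in sero-surveys vs 88.7% in clinics;
#' ten-cell-leader names 48.3%/48.3% vs 91.5%/74.6%; household-member names
#' 71.5% vs 11.3%; village and sub-village 100% vs 99.3%). Birth month/day
#' completeness is not reported there and defaults to 0.95/0.90.
#'
#' @return named list with elements `sero_survey` and `clinic`, each a named
#'   vector of presence probabilities.
#' @export
default_completeness <- function() {
  list(
    sero_survey = c(name_1 = 1, name_2 = 1, name_3 = 0.133,
                    birth_year = 1, birth_month = 0.95, birth_day = 0.95,
                    sex = 1, village = 1, sub_village = 1,
                    tcl_name_1 = 0.483, tcl_name_2 = 0.483,
                    hh_member_name_1 = 0.715, hh_member_name_2 = 0.715),
    clinic = c(name_1 = 1, name_2 = 1, name_3 = 0.887,
               birth_year = 1, birth_month = 0.90, birth_day = 0.90,
               sex = 1, village = 0.993, sub_village = 0.993,
               tcl_name_1 = 0.915, tcl_name_2 = 0.746,
               hh_member_name_1 = 0.113, hh_member_name_2 = 0.113)
  )
}

# One random typo per name: substitution, transposition or deletion,
# position uniform. Single-character names can only be substituted.
apply_typo <- function(names) {
  vapply(names, function(nm) {
    if (is.na(nm) || nchar(nm) == 0) return(nm)
    ch <- strsplit(nm, "")[[1]]
    L <- length(ch)
    op <- if (L < 2) "sub" else sample(c("sub", "trans", "del"), 1)
    if (op == "sub") {
      i <- sample.int(L, 1)
      repl <- sample(LETTERS, 1)
      while (repl == ch[i]) repl <- sample(LETTERS, 1)
      ch[i] <- repl
    } else if (op == "trans") {
      i <- sample.int(L - 1L, 1)
      ch[c(i, i + 1L)] <- ch[c(i + 1L, i)]
    } else {
      ch <- ch[-sample.int(L, 1)]
    }
    paste(ch, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

completeness_for <- function(corruption, source) {
  key <- if (source == "sero_survey") "sero_survey" else "clinic"
  corruption$completeness[[key]]
}

#' Derive corrupted encounter records from registry persons
#'
#' Applies the configured error and missingness processes to each person's
#' identifiers, producing one encounter record per input row. With all error
#' rates zero and completeness one, encounter identifiers equal the person's
#' exactly. `gold_person_id` always records the generating person.
#'
#' @param persons data frame of registry persons (rows of
#'   `registry$persons`).
#' @param source encounter source for each row: `"sero_survey"`, `"HTC"` or
#'   `"ANC"` (recycled if length 1). HTC and ANC share the clinic
#'   completeness profile.
#' @param corruption a [corruption_config()].
#' @return data frame of encounter records; absent fields are `NA`.
#' @export
corrupt_encounter <- function(persons, source, corruption = corruption_config()) {
  stopifnot(inherits(corruption, "corruption_config"))
  n <- nrow(persons)
  source <- rep_len(as.character(source), n)
  if (!all(source %in% ENC_SOURCES))
    stop("source must be one of: ", paste(ENC_SOURCES, collapse = ", "))

  pool3 <- name_pool(60, "given")
  enc <- data.frame(encounter_id = sprintf("E%06d", seq_len(n)),
                    source = source, stringsAsFactors = FALSE)

  # presence masks per row (clinic profile shared by HTC/ANC)
  comp <- t(vapply(source, function(s) completeness_for(corruption, s),
                   numeric(13)))
  present <- matrix(runif(n * 13) < comp, n, 13,
                    dimnames = list(NULL, colnames(comp)))
  # second TCL / household-member names nested within the first
  for (pair in list(c("tcl_name_1", "tcl_name_2"),
                    c("hh_member_name_1", "hh_member_name_2"))) {
    p1 <- comp[, pair[1]]; p2 <- comp[, pair[2]]
    cond <- ifelse(p1 > 0, pmin(p2 / p1, 1), 0)
    present[, pair[2]] <- present[, pair[1]] & (runif(n) < cond)
  }

  n1 <- persons$name_1
  n2 <- persons$name_2
  swap <- runif(n) < corruption$name_swap_rate
  tmp <- n1[swap]; n1[swap] <- n2[swap]; n2[swap] <- tmp
  typo <- function(x) {
    hit <- !is.na(x) & runif(length(x)) < corruption$typo_rate
    x[hit] <- apply_typo(x[hit])
    x
  }
  enc$name_1 <- ifelse(present[, "name_1"], typo(n1), NA)
  enc$name_2 <- ifelse(present[, "name_2"], typo(n2), NA)
  # an extra reported name the registry does not hold
  enc$name_3 <- ifelse(present[, "name_3"],
                       sample(pool3, n, replace = TRUE), NA)

  sexv <- persons$sex
  flip <- runif(n) < corruption$sex_error_rate
  sexv[flip] <- ifelse(sexv[flip] == "F", "M", "F")
  enc$sex <- ifelse(present[, "sex"], sexv, NA)

  by <- persons$birth_year
  hit <- !is.na(by) & runif(n) < corruption$birth_year_error_rate
  if (any(hit)) {
    shift <- round(rnorm(sum(hit), 0, corruption$birth_year_error_sd))
    shift <- ifelse(shift == 0, sample(c(-1L, 1L), sum(hit), replace = TRUE),
                    shift)
    by[hit] <- by[hit] + shift
  }
  enc$birth_year <- ifelse(present[, "birth_year"], by, NA)
  bm <- persons$birth_month
  hit <- runif(n) < corruption$birth_md_error_rate
  bm[hit] <- sample(1:12, sum(hit), replace = TRUE)
  enc$birth_month <- ifelse(present[, "birth_month"], bm, NA)
  bd <- persons$birth_day
  hit <- runif(n) < corruption$birth_md_error_rate
  bd[hit] <- sample(1:28, sum(hit), replace = TRUE)
  enc$birth_day <- ifelse(present[, "birth_day"], bd, NA)

  vil <- persons$village
  svl <- persons$sub_village
  hit <- runif(n) < corruption$geo_error_rate
  if (any(hit)) {
    alt <- sample(seq_len(n), sum(hit), replace = TRUE)
    vil[hit] <- persons$village[alt]
    svl[hit] <- persons$sub_village[alt]
  }
  enc$village <- ifelse(present[, "village"], vil, NA)
  enc$sub_village <- ifelse(present[, "sub_village"], svl, NA)

  enc$tcl_name_1 <- ifelse(present[, "tcl_name_1"],
                           typo(persons$tcl_name_1), NA)
  enc$tcl_name_2 <- ifelse(present[, "tcl_name_2"],
                           typo(persons$tcl_name_2), NA)
  enc$tcl_name_3 <- NA_character_
  enc$hh_member_name_1 <- ifelse(present[, "hh_member_name_1"],
                                 typo(persons$hh_member_name_1), NA)
  enc$hh_member_name_2 <- ifelse(present[, "hh_member_name_2"],
                                 typo(persons$hh_member_name_2), NA)
  enc$hh_member_name_3 <- NA_character_
  enc$gold_person_id <- persons$person_id
  enc
}

#' Outcome-model configuration
#'
#' Defines the exposure (testing modality: community sero-survey vs walk-in
#' clinic), the true modality effect on the hazard of HIV-care registration,
#' covariate effects, and the censoring scheme (death or 90 days after
#' diagnosis). Defaults mirror the study cohort: 405 first diagnoses split
#' 263:142 between sero-survey and clinic (HTC share 88.7% of clinic
#' diagnoses), with modality-conditional covariate mixtures matching the
#' descriptive table of the analytic sample.
#'
#' @param true_log_hr_modality log hazard ratio of registration, clinic vs
#'   sero-survey diagnosis. Default `log(5)`.
#' @param covariate_log_hrs named list of per-level log hazard ratios
#'   (reference levels: 15-29, F, rural, no paved road, <1 km).
#' @param baseline_hazard_rate registration events/day at reference levels
#'   in the sero-survey arm. The default 0.0019 gives ~16% registering
#'   within 90 days in the reference arm.
#' @param admin_censor_days administrative censoring horizon (days).
#' @param death_rate death events/day (competing censoring).
#' @param background_registration_rate events/day at which a registry person
#'   who is not the encounter's true person registers for care; this is the
#'   history a falsely linked record inherits.
#' @param n_cohort number of eligible diagnosed individuals.
#' @param modality_split proportion of diagnoses in the sero-survey.
#' @param clinic_htc_share share of clinic diagnoses made at the HTC (the
#'   rest at the ANC).
#' @param covariate_mixture per-modality target distributions for age group,
#'   sex, rurality, paved road and distance band.
#' @param ineligible_rates extra encounters appended per eligible cohort
#'   member, by exclusion reason, so eligibility filtering is exercisable.
#' @return an `outcome_config` list.
#' @export
outcome_config <- function(true_log_hr_modality = log(5),
                           covariate_log_hrs = default_covariate_log_hrs(),
                           baseline_hazard_rate = 0.0019,
                           admin_censor_days = 90L,
                           death_rate = 3e-4,
                           background_registration_rate = 5e-4,
                           n_cohort = 405L,
                           modality_split = 263 / 405,
                           clinic_htc_share = 0.887,
                           covariate_mixture = default_covariate_mixture(),
                           ineligible_rates = c(under_15 = 0.04,
                                                repeat_tester = 0.05,
                                                non_resident = 0.04)) {
  if (baseline_hazard_rate < 0 || death_rate < 0 ||
      background_registration_rate < 0)
    stop("outcome_config: rates must be nonnegative")
  if (modality_split < 0 || modality_split > 1)
    stop("outcome_config: 'modality_split' must be in [0, 1]")
  for (nm in names(covariate_mixture)) {
    for (mod in MODALITY_LEVELS) {
      p <- covariate_mixture[[nm]][[mod]]
      if (abs(sum(p) - 1) > 1e-6)
        stop("outcome_config: mixture '", nm, "' (", mod,
             ") must sum to 1")
    }
  }
  cfg <- list(true_log_hr_modality = true_log_hr_modality,
              covariate_log_hrs = covariate_log_hrs,
              baseline_hazard_rate = baseline_hazard_rate,
              admin_censor_days = as.integer(admin_censor_days),
              death_rate = death_rate,
              background_registration_rate = background_registration_rate,
              n_cohort = as.integer(n_cohort),
              modality_split = modality_split,
              clinic_htc_share = clinic_htc_share,
              covariate_mixture = covariate_mixture,
              ineligible_rates = ineligible_rates)
  class(cfg) <- "outcome_config"
  cfg
}

#' @rdname outcome_config
#' @export
default_covariate_log_hrs <- function() {
  list(age_group = c("30-39" = -0.10, "40-49" = -0.20, "50+" = -0.30),
       sex = c(M = -0.10),
       rurality = c(peri_urban = 0.10, urban = 0.15),
       paved_road = c(`TRUE` = 0.10),
       distance_band = c("1-1.9" = -0.10, "2-4.9" = -0.20, "5-11" = -0.30))
}

#' @rdname outcome_config
#' @export
default_covariate_mixture <- function() {
  list(
    age_group = list(sero_survey = setNames(c(62, 96, 59, 46) / 263, AGE_LEVELS),
                     clinic = setNames(c(51, 53, 22, 16) / 142, AGE_LEVELS)),
    sex = list(sero_survey = c(F = 173, M = 90) / 263,
               clinic = c(F = 98, M = 44) / 142),
    rurality = list(sero_survey = setNames(c(140, 54, 69) / 263, RURALITY_LEVELS),
                    clinic = setNames(c(55, 39, 48) / 142, RURALITY_LEVELS)),
    paved_road = list(sero_survey = c(`FALSE` = 154, `TRUE` = 109) / 263,
                      clinic = c(`FALSE` = 72, `TRUE` = 70) / 142),
    distance_band = list(sero_survey = setNames(c(53, 58, 60, 92) / 263, DIST_LEVELS),
                         clinic = setNames(c(37, 45, 29, 31) / 142, DIST_LEVELS))
  )
}

# Importance weights reproducing the modality-conditional covariate targets
# over the eligible registry pool (ratio of target to empirical frequency,
# multiplied across covariates).
mixture_weights <- function(pool, mixture, modality) {
  w <- rep(1, nrow(pool))
  for (nm in names(mixture)) {
    x <- as.character(pool[[nm]])
    target <- mixture[[nm]][[modality]]
    emp <- table(factor(x, levels = names(target))) / length(x)
    ratio <- ifelse(emp[names(target)] > 0, target / as.numeric(emp), 0)
    w <- w * as.numeric(ratio[x])
  }
  w[!is.finite(w)] <- 0
  w
}

age_group_of <- function(age) {
  cut(age, breaks = c(-Inf, 30, 40, 50, Inf), labels = AGE_LEVELS,
      right = FALSE)
}

#' Simulate a diagnosed cohort with outcomes and gold-standard links
#'
#' Samples diagnosed individuals from the registry with modality-dependent
#' covariate mixtures, draws exponential proportional-hazards
#' time-to-registration outcomes with death and administrative censoring,
#' emits corrupted encounter records with gold links, and appends ineligible
#' encounters (under 15, repeat testers, non-residents) at the configured
#' rates. Every registry person additionally receives a latent background
#' registration/death history, which is what a falsely linked encounter
#' inherits downstream.
#'
#' @param registry an `hdss_registry` from [generate_population()].
#' @param outcome an [outcome_config()].
#' @param corruption a [corruption_config()].
#' @param seed integer RNG seed.
#' @return list with `encounters`, `gold_links` (encounter_id, person_id),
#'   `outcomes` (one row per eligible cohort member with covariates,
#'   `time_days`, `event`), and `latent` (per-person background offsets).
#' @export
simulate_cohort <- function(registry, outcome = outcome_config(),
                            corruption = corruption_config(), seed = 1L) {
  stopifnot(inherits(registry, "hdss_registry"))
  persons <- registry$persons
  if (nrow(persons) == 0) stop("registry is empty")
  set.seed(seed)

  n_coh <- outcome$n_cohort
  n_sero <- round(n_coh * outcome$modality_split)
  n_clin <- n_coh - n_sero

  # eligible pool: adults by day 0, complete covariates
  age0 <- floor(EPOCH_YEAR) - persons$birth_year
  pool <- persons[!is.na(age0) & age0 >= 16, , drop = FALSE]
  pool$age_group <- as.character(age_group_of(floor(EPOCH_YEAR) - pool$birth_year))
  if (nrow(pool) < n_coh + 10)
    stop("registry too small for the configured cohort size")

  pick <- function(modality, n_pick, exclude) {
    avail <- setdiff(seq_len(nrow(pool)), exclude)
    w <- mixture_weights(pool[avail, , drop = FALSE],
                         outcome$covariate_mixture, modality)
    if (all(w == 0)) w <- rep(1, length(avail))
    avail[sample.int(length(avail), n_pick, prob = w)]
  }
  i_sero <- pick("sero_survey", n_sero, integer(0))
  i_clin <- pick("clinic", n_clin, i_sero)
  idx <- c(i_sero, i_clin)
  coh <- pool[idx, , drop = FALSE]
  coh$modality <- rep(MODALITY_LEVELS, c(n_sero, n_clin))
  coh$source <- ifelse(coh$modality == "sero_survey", "sero_survey",
                       ifelse(runif(n_coh) < outcome$clinic_htc_share,
                              "HTC", "ANC"))
  coh$diagnosis_day <- sample(0:STUDY_DAYS, n_coh, replace = TRUE)
  coh$age_at_encounter <- floor(EPOCH_YEAR + coh$diagnosis_day / 365.25 -
                                  coh$birth_year)
  coh$age_group <- as.character(age_group_of(coh$age_at_encounter))

  # linear predictor and latent times
  lhr <- outcome$covariate_log_hrs
  lp <- outcome$true_log_hr_modality * (coh$modality == "clinic")
  lp <- lp + ifelse(coh$age_group %in% names(lhr$age_group),
                    lhr$age_group[coh$age_group], 0)
  lp <- lp + ifelse(coh$sex %in% names(lhr$sex), lhr$sex[coh$sex], 0)
  lp <- lp + ifelse(coh$rurality %in% names(lhr$rurality),
                    lhr$rurality[coh$rurality], 0)
  lp <- lp + ifelse(coh$paved_road, lhr$paved_road[["TRUE"]], 0)
  lp <- lp + ifelse(coh$distance_band %in% names(lhr$distance_band),
                    lhr$distance_band[coh$distance_band], 0)
  t_reg <- rexp(n_coh, outcome$baseline_hazard_rate * exp(lp))
  t_death <- if (outcome$death_rate > 0) rexp(n_coh, outcome$death_rate)
             else rep(Inf, n_coh)
  horizon <- outcome$admin_censor_days
  tt <- build_time_to_event(rep(0, n_coh),
                            ifelse(t_reg <= t_death, t_reg, NA),
                            ifelse(t_death < t_reg, t_death, NA),
                            admin_days = horizon)
  coh$time_days <- tt$time_days
  coh$event <- tt$event
  coh$registration_day <- ifelse(coh$event == 1,
                                 coh$diagnosis_day + coh$time_days, NA)
  coh$prior_positive_flag <- FALSE
  coh$resident <- TRUE

  # ineligible extras
  extras <- list()
  n_u15 <- round(outcome$ineligible_rates[["under_15"]] * n_coh)
  kid_age <- floor(EPOCH_YEAR) - persons$birth_year
  kids <- persons[!is.na(kid_age) & kid_age < 15, , drop = FALSE]
  if (n_u15 > 0 && nrow(kids) > 0) {
    k <- kids[sample.int(nrow(kids), min(n_u15, nrow(kids))), , drop = FALSE]
    k$prior_positive_flag <- FALSE; k$resident <- TRUE
    extras$under_15 <- k
  }
  rest <- pool[-idx, , drop = FALSE]
  n_rep <- round(outcome$ineligible_rates[["repeat_tester"]] * n_coh)
  if (n_rep > 0 && nrow(rest) >= n_rep) {
    k <- rest[sample.int(nrow(rest), n_rep), , drop = FALSE]
    k$prior_positive_flag <- TRUE; k$resident <- TRUE
    extras$repeat_tester <- k
    rest <- rest[!(rest$person_id %in% k$person_id), , drop = FALSE]
  }
  n_nr <- round(outcome$ineligible_rates[["non_resident"]] * n_coh)
  if (n_nr > 0 && nrow(rest) >= n_nr) {
    k <- rest[sample.int(nrow(rest), n_nr), , drop = FALSE]
    k$prior_positive_flag <- FALSE; k$resident <- FALSE
    extras$non_resident <- k
  }
  extra <- if (length(extras)) do.call(rbind, lapply(extras, function(d)
    d[, c("person_id", "birth_year", "prior_positive_flag", "resident"),
      drop = FALSE])) else NULL

  all_persons <- persons[match(c(coh$person_id,
                                 if (!is.null(extra)) extra$person_id),
                               persons$person_id), , drop = FALSE]
  n_all <- nrow(all_persons)
  src <- c(coh$source,
           if (!is.null(extra))
             sample(ENC_SOURCES, nrow(extra), replace = TRUE,
                    prob = c(0.5, 0.4, 0.1)))
  enc <- corrupt_encounter(all_persons, src, corruption)
  enc$diagnosis_date <- c(coh$diagnosis_day,
                          if (!is.null(extra))
                            sample(0:STUDY_DAYS, nrow(extra), replace = TRUE))
  enc$age_at_encounter <- floor(EPOCH_YEAR + enc$diagnosis_date / 365.25) -
    all_persons$birth_year
  enc$prior_positive_flag <- c(coh$prior_positive_flag,
                               if (!is.null(extra)) extra$prior_positive_flag)
  enc$resident <- c(coh$resident, if (!is.null(extra)) extra$resident)

  gold_links <- data.frame(encounter_id = enc$encounter_id,
                           person_id = enc$gold_person_id,
                           stringsAsFactors = FALSE)

  outcomes <- data.frame(encounter_id = enc$encounter_id[seq_len(n_coh)],
                         person_id = coh$person_id,
                         modality = coh$modality,
                         source = coh$source,
                         age_group = coh$age_group,
                         sex = coh$sex,
                         rurality = coh$rurality,
                         paved_road = coh$paved_road,
                         distance_band = coh$distance_band,
                         diagnosis_day = coh$diagnosis_day,
                         time_days = coh$time_days,
                         event = coh$event,
                         stringsAsFactors = FALSE)

  latent <- data.frame(person_id = persons$person_id,
                       bg_reg_offset =
                         if (outcome$background_registration_rate > 0)
                           rexp(nrow(persons),
                                outcome$background_registration_rate)
                         else rep(Inf, nrow(persons)),
                       bg_death_offset =
                         if (outcome$death_rate > 0)
                           rexp(nrow(persons), outcome$death_rate)
                         else rep(Inf, nrow(persons)),
                       stringsAsFactors = FALSE)

  list(encounters = enc, gold_links = gold_links, outcomes = outcomes,
       latent = latent)
}

#' Build a complete synthetic linkage world
#'
#' Convenience wrapper: generates a registry and simulates a diagnosed
#' cohort on it, returning everything downstream stages need.
#'
#' @param pop a [population_config()].
#' @param outcome an [outcome_config()].
#' @param corruption a [corruption_config()].
#' @param seed integer RNG seed (registry uses `seed`, cohort `seed + 1`).
#' @return object of class `linkerr_world`.
#' @export
make_world <- function(pop = population_config(),
                       outcome = outcome_config(),
                       corruption = corruption_config(), seed = 1L) {
  registry <- generate_population(pop, seed)
  sim <- simulate_cohort(registry, outcome, corruption, seed + 1L)
  structure(c(list(registry = registry), sim,
              list(outcome_config = outcome, corruption_config = corruption,
                   seed = seed)),
            class = "linkerr_world")
}

#' @export
print.linkerr_world <- function(x, ...) {
  cat("<linkerr_world> registry of ", nrow(x$registry$persons),
      " persons; ", nrow(x$encounters), " encounters (",
      nrow(x$outcomes), " eligible)\n", sep = "")
  invisible(x)
}
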