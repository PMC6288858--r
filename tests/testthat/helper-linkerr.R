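# Shared fixtures and independent reference implementations.

# Pure-R Jaro-Winkler, written directly from the textbook definition; the
# independent oracle for the compiled comparator.
jw_ref <- function(a, b, prefix_scale = 0.1, max_prefix = 4) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  la <- length(ca); lb <- length(cb)
  if (la == 0 || lb == 0) return(0)
  win <- max(floor(max(la, lb) / 2) - 1, 0)
  ma <- logical(la); mb <- logical(lb)
  for (i in seq_len(la)) {
    for (j in seq(max(1, i - win), min(lb, i + win))) {
      if (!mb[j] && ca[i] == cb[j]) { ma[i] <- TRUE; mb[j] <- TRUE; break }
    }
  }
  m <- sum(ma)
  if (m == 0) return(0)
  t <- sum(ca[ma] != cb[mb]) / 2
  jaro <- (m / la + m / lb + (m - t) / m) / 3
  p <- 0
  while (p < min(la, lb, max_prefix) && ca[p + 1] == cb[p + 1]) p <- p + 1
  jaro + p * prefix_scale * (1 - jaro)
}

# Corruption that copies identifiers verbatim: all error rates zero, all
# fields fully recorded (no spurious third name).
perfect_corruption <- function() {
  comp <- default_completeness()
  for (s in names(comp)) {
    comp[[s]][] <- 1
    comp[[s]]["name_3"] <- 0
  }
  corruption_config(typo_rate = 0, name_swap_rate = 0,
                    birth_year_error_rate = 0, birth_md_error_rate = 0,
                    sex_error_rate = 0, geo_error_rate = 0,
                    completeness = comp)
}

# Registry with every matching identifier present on every person, so that
# under perfect corruption all true-pair scores are identical.
complete_registry <- function(n = 300, seed = 11) {
  reg <- generate_population(
    population_config(n = n, hdss_completeness = c(birth_year = 1,
                                                   tcl_name = 1,
                                                   hh_member_name = 1)),
    seed = seed)
  p <- reg$persons
  solo <- is.na(p$hh_member_name_1)
  p$hh_member_name_1[solo] <- p$name_1[solo]
  p$hh_member_name_2[solo] <- p$name_2[solo]
  reg$persons <- p
  reg
}

# Fully assembled world under perfect recording.
perfect_world <- function(n = 300, n_cohort = 80, seed = 11) {
  reg <- complete_registry(n, seed)
  outc <- outcome_config(n_cohort = n_cohort,
                         ineligible_rates = c(under_15 = 0, repeat_tester = 0,
                                              non_resident = 0))
  sim <- simulate_cohort(reg, outc, perfect_corruption(), seed + 1)
  structure(c(list(registry = reg), sim,
              list(outcome_config = outc,
                   corruption_config = perfect_corruption(), seed = seed)),
            class = "linkerr_world")
}

# Small default-corruption world for fast pipeline tests.
small_world <- function(seed = 21, n = 800, n_cohort = 120) {
  make_world(population_config(n = n),
             outcome_config(n_cohort = n_cohort),
             corruption_config(), seed = seed)
}

# Exhaustive best-candidate search through the R-level scorer; the
# independent oracle for the compiled linkage engine. Returns the maximal
# score and (first) argmax person per encounter under the same tie-break
# (fewest disagreements, then lowest person_id).
brute_force_links <- function(encounters, persons, params = match_params()) {
  persons <- persons[order(persons$person_id), , drop = FALSE]
  enc_l <- lapply(seq_len(nrow(encounters)),
                  function(i) as.list(encounters[i, , drop = FALSE]))
  per_l <- lapply(seq_len(nrow(persons)),
                  function(i) as.list(persons[i, , drop = FALSE]))
  out <- lapply(enc_l, function(e) {
    best <- NULL
    for (p in per_l) {
      cp <- score_pair(e, p, params)
      dis <- sum(cp$outcomes == "disagree")
      if (is.null(best) || cp$match_score > best$score + 1e-9 ||
          (cp$match_score > best$score - 1e-9 && dis < best$dis)) {
        best <- list(person_id = p$person_id, score = cp$match_score,
                     dis = dis)
      }
    }
    data.frame(encounter_id = e$encounter_id, person_id = best$person_id,
               match_score = best$score, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
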