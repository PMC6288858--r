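test_that("identical config and seed reproduce identical outputs", {
  cfg <- population_config(n = 400)
  r1 <- generate_population(cfg, seed = 7)
  r2 <- generate_population(cfg, seed = 7)
  expect_identical(r1, r2)
  s1 <- simulate_cohort(r1, outcome_config(n_cohort = 60),
                        corruption_config(), seed = 3)
  s2 <- simulate_cohort(r2, outcome_config(n_cohort = 60),
                        corruption_config(), seed = 3)
  expect_identical(s1, s2)
})

test_that("degenerate configurations are rejected with the offending field", {
  expect_error(generate_population(population_config(n = 0)), "'n'")
  expect_error(generate_population(population_config(pool_size_given = 0)),
               "pool")
  expect_error(corruption_config(typo_rate = 1.5), "\\[0, 1\\]")
  expect_error(outcome_config(baseline_hazard_rate = -1), "nonnegative")
  expect_error(simulate_cohort(structure(list(persons = data.frame()),
                                         class = "hdss_registry")),
               "empty")
})

test_that("registry invariants hold: ids, households, episodes", {
  reg <- generate_population(population_config(n = 2000), seed = 13)
  p <- reg$persons
  expect_false(anyDuplicated(p$person_id) > 0)
  # household members share location, ten-cell leader and coordinates
  for (col in c("sub_village", "tcl_name_1", "x_km", "y_km")) {
    n_distinct <- tapply(p[[col]], p$household_id,
                         function(x) length(unique(x[!is.na(x)])))
    expect_true(all(n_distinct <= 1), info = col)
  }
  # residency episodes of one person do not overlap
  ep <- reg$episodes
  by_person <- split(ep, ep$person_id)
  overlaps <- vapply(by_person, function(e) {
    if (nrow(e) < 2) return(FALSE)
    e <- e[order(e$start_day), ]
    ends <- ifelse(is.na(e$end_day), Inf, e$end_day)
    any(e$start_day[-1] < ends[-nrow(e)])
  }, logical(1))
  expect_false(any(overlaps))
})

test_that("finite name pools force duplicate full names at scale", {
  reg <- generate_population(population_config(n = 10000), seed = 9)
  full <- paste(reg$persons$name_1, reg$persons$name_2)
  expect_gt(sum(duplicated(full)), 0)
})

test_that("zero corruption and full completeness copy identifiers verbatim", {
  reg <- complete_registry(n = 200, seed = 5)
  set.seed(1)
  enc <- corrupt_encounter(reg$persons, "sero_survey", perfect_corruption())
  for (f in c("name_1", "name_2", "sex", "birth_year", "birth_month",
              "birth_day", "village", "sub_village", "tcl_name_1",
              "tcl_name_2", "hh_member_name_1", "hh_member_name_2")) {
    expect_identical(enc[[f]], reg$persons[[f]], info = f)
  }
  expect_identical(enc$gold_person_id, reg$persons$person_id)
})

test_that("observed field completeness matches the configured probability", {
  reg <- generate_population(population_config(n = 10000), seed = 17)
  set.seed(2)
  enc <- corrupt_encounter(reg$persons, "sero_survey", corruption_config())
  comp <- default_completeness()$sero_survey
  # completeness applies to identifiers the registry actually holds, so
  # condition on a non-missing source value for the person-level fields
  obs <- function(enc, f) {
    has <- if (f %in% names(reg$persons)) !is.na(reg$persons[[f]])
           else rep(TRUE, nrow(enc))
    mean(!is.na(enc[[f]][has]))
  }
  for (f in c("name_3", "tcl_name_1", "hh_member_name_1")) {
    p <- comp[[f]]
    se3 <- 3 * sqrt(p * (1 - p) / nrow(enc))
    expect_lt(abs(obs(enc, f) - p), se3 + 1e-12, label = f)
  }
  # clinic profile, including the nested second TCL name marginal
  set.seed(3)
  encc <- corrupt_encounter(reg$persons, "HTC", corruption_config())
  compc <- default_completeness()$clinic
  for (f in c("name_3", "tcl_name_1", "tcl_name_2")) {
    p <- compc[[f]]
    se3 <- 3 * sqrt(p * (1 - p) / nrow(encc))
    expect_lt(abs(obs(encc, f) - p), se3 + 1e-12, label = f)
  }
})

test_that("typo_rate 1 corrupts every recorded name", {
  reg <- generate_population(population_config(n = 300), seed = 23)
  cor1 <- perfect_corruption()
  cor1$typo_rate <- 1
  set.seed(4)
  enc <- corrupt_encounter(reg$persons, "HTC", cor1)
  expect_true(all(enc$name_1 != reg$persons$name_1))
  expect_true(all(enc$name_2 != reg$persons$name_2))
})

test_that("cohort outcomes respect the survival contract", {
  w <- small_world(seed = 31)
  oc <- w$outcomes
  expect_true(all(oc$time_days > 0))
  expect_true(all(oc$time_days <= 90))
  expect_true(all(oc$event %in% c(0, 1)))
  # gold links are a function of encounters
  expect_false(anyDuplicated(w$gold_links$encounter_id) > 0)
  expect_true(all(w$gold_links$person_id %in% w$registry$persons$person_id))
  # ineligible records present for all three exclusion reasons
  el <- apply_eligibility(w$encounters)
  excl <- attr(el, "exclusions")
  expect_true(all(excl > 0))
  expect_setequal(el$encounter_id[el$encounter_id %in% oc$encounter_id],
                  oc$encounter_id)
})

test_that("null modality effect yields symmetric registration curves", {
  null_lhr <- default_covariate_log_hrs()
  null_lhr <- lapply(null_lhr, function(x) { x[] <- 0; x })
  outc <- outcome_config(true_log_hr_modality = 0,
                         covariate_log_hrs = null_lhr,
                         n_cohort = 2000, modality_split = 0.5)
  reg <- generate_population(population_config(n = 6000), seed = 41)
  sim <- simulate_cohort(reg, outc, corruption_config(), seed = 42)
  sd_ <- survival::survdiff(
    survival::Surv(time_days, event) ~ modality, data = sim$outcomes)
  expect_gt(1 - stats::pchisq(sd_$chisq, 1), 0.01)
})

test_that("administrative censoring truncates at the configured horizon", {
  outc <- outcome_config(n_cohort = 200, admin_censor_days = 45)
  reg <- generate_population(population_config(n = 1000), seed = 51)
  sim <- simulate_cohort(reg, outc, corruption_config(), seed = 52)
  expect_true(all(sim$outcomes$time_days <= 45))
})
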