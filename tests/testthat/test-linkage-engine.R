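test_that("field weights follow the closed-form log-likelihood ratios", {
  expect_equal(field_weight("agree", 0.9, 0.05), log2(18), tolerance = 1e-12)
  expect_equal(field_weight("disagree", 0.9, 0.05), log2(0.1 / 0.95),
               tolerance = 1e-12)
  expect_equal(field_weight("agree", 0.9, 0.05), 4.1699, tolerance = 1e-4)
  expect_equal(field_weight("disagree", 0.9, 0.05), -3.2479, tolerance = 1e-4)
  # no-information limit: m -> u from above
  expect_lt(abs(field_weight("agree", 0.3 + 1e-9, 0.3)), 1e-8)
  expect_error(field_weight("agree", 0.2, 0.5), "m > u")
  expect_error(match_params(m = c(name = 0.04, sex = 0.95, birth_year = 0.9,
                                  birth_month = 0.9, birth_day = 0.9,
                                  village = 0.95, sub_village = 0.95,
                                  hh_member_name = 0.9, tcl_name = 0.9)),
               "name")
})

test_that("name-field agreement is order-relaxed and handles absence", {
  p <- match_params()
  r <- name_field_agreement(c("JOHN", "DOE"), c("DOE", "JOHN"), p)
  expect_identical(r$outcome, "agree")
  expect_identical(r$best_similarity, 1)
  r <- name_field_agreement("MARTHA", "MARHTA", p)
  expect_identical(r$outcome, "agree")
  expect_equal(r$best_similarity, 0.9611, tolerance = 1e-4)
  expect_identical(name_field_agreement(character(0), "DOE", p)$outcome,
                   "missing")
  expect_identical(name_field_agreement(NA_character_, "DOE", p)$outcome,
                   "missing")
  expect_identical(name_field_agreement("ABC", "XYZ", p)$outcome, "disagree")
})

make_rec <- function(id = "E1", pid = "P1", name_1 = NA, name_2 = NA,
                     name_3 = NA, sex = NA, birth_year = NA, birth_month = NA,
                     birth_day = NA, village = NA, sub_village = NA,
                     tcl_name_1 = NA, tcl_name_2 = NA, hh_member_name_1 = NA,
                     hh_member_name_2 = NA) {
  list(encounter_id = id, person_id = pid, name_1 = name_1, name_2 = name_2,
       name_3 = name_3, sex = sex, birth_year = birth_year,
       birth_month = birth_month, birth_day = birth_day, village = village,
       sub_village = sub_village, tcl_name_1 = tcl_name_1,
       tcl_name_2 = tcl_name_2, hh_member_name_1 = hh_member_name_1,
       hh_member_name_2 = hh_member_name_2)
}

uniform_params <- function(m = 0.9, u = 0.05) {
  fields <- c("name", "sex", "birth_year", "birth_month", "birth_day",
              "village", "sub_village", "hh_member_name", "tcl_name")
  match_params(m = setNames(rep(m, 9), fields),
               u = setNames(rep(u, 9), fields))
}

test_that("pair scores sum field weights over non-missing fields", {
  p <- uniform_params()
  # five comparable fields, all agreeing
  enc <- make_rec(name_1 = "JOHN", sex = "M", birth_year = 1980,
                  village = "V1", sub_village = "SV1")
  per <- make_rec(name_1 = "JOHN", sex = "M", birth_year = 1980,
                  village = "V1", sub_village = "SV1")
  cp <- score_pair(enc, per, p)
  expect_equal(cp$match_score, 5 * log2(18), tolerance = 1e-10)
  expect_equal(cp$match_score, 20.849, tolerance = 1e-3)
  expect_identical(unname(cp$outcomes[c("name", "sex", "birth_year",
                                        "village", "sub_village")]),
                   rep("agree", 5))
  # same five fields, all disagreeing
  per2 <- make_rec(name_1 = "XYZ", sex = "F", birth_year = 1950,
                   village = "V2", sub_village = "SV9")
  cp2 <- score_pair(enc, per2, p)
  expect_equal(cp2$match_score, 5 * log2(0.1 / 0.95), tolerance = 1e-10)
  expect_equal(cp2$match_score, -16.239, tolerance = 1e-3)
  # empty encounter: every field missing, zero score
  cp3 <- score_pair(make_rec(), per, p)
  expect_identical(cp3$match_score, 0)
  expect_true(all(cp3$outcomes == "missing"))
})

test_that("scores are invariant to listed-name order and monotone in agreement", {
  p <- match_params()
  enc <- make_rec(name_1 = "MAJU", name_2 = "RAKA", name_3 = "NELI",
                  sex = "F", birth_year = 1970, village = "V1",
                  sub_village = "S1")
  per <- make_rec(name_1 = "RAKA", name_2 = "MAJU", sex = "F",
                  birth_year = 1970, village = "V1", sub_village = "S1")
  base <- score_pair(enc, per, p)$match_score
  for (perm in list(c(2, 1, 3), c(3, 1, 2), c(2, 3, 1))) {
    enc2 <- enc
    enc2[c("name_1", "name_2", "name_3")] <-
      enc[c("name_1", "name_2", "name_3")][perm]
    expect_equal(score_pair(enc2, per, p)$match_score, base,
                 tolerance = 1e-12)
  }
  # raising a single field from disagree to agree never lowers the score
  enc3 <- enc; enc3$sex <- "M"
  expect_lt(score_pair(enc3, per, p)$match_score, base)
})

test_that("best-candidate selection dominates on exact matches and flags ties", {
  reg <- complete_registry(n = 150, seed = 3)
  set.seed(9)
  enc <- corrupt_encounter(reg$persons[1:40, ], "sero_survey",
                           perfect_corruption())
  best <- link_best_candidates(enc, reg)
  expect_identical(best$person_id, enc$gold_person_id)
  expect_true(all(best$tie == FALSE))

  # duplicated person: deterministic tie-break to the lower person_id
  dup <- reg$persons[1, , drop = FALSE]
  dup$person_id <- "P999999"
  reg2 <- reg
  reg2$persons <- rbind(reg$persons, dup)
  b2 <- link_best_candidates(enc[1, , drop = FALSE], reg2)
  expect_identical(b2$person_id, reg$persons$person_id[1])
  expect_true(b2$tie)
})

test_that("compiled linkage equals exhaustive score maximisation", {
  reg <- generate_population(population_config(n = 500), seed = 19)
  set.seed(7)
  enc <- corrupt_encounter(reg$persons[sample.int(500, 50), ],
                           "HTC", corruption_config())
  fast <- link_best_candidates(enc, reg)
  slow <- brute_force_links(enc, reg$persons)
  expect_equal(fast$match_score, slow$match_score, tolerance = 1e-9)
  expect_identical(fast$person_id, slow$person_id)
  expect_error(link_best_candidates(enc, data.frame()), "empty")
})

test_that("blocked linkage agrees with full linkage when blocks are respected", {
  reg <- generate_population(population_config(n = 400), seed = 29)
  set.seed(8)
  cfg <- corruption_config(sex_error_rate = 0, geo_error_rate = 0)
  enc <- corrupt_encounter(reg$persons[1:25, ], "sero_survey", cfg)
  full <- link_best_candidates(enc, reg)
  blk <- link_best_candidates(enc, reg, block = TRUE)
  agree_on_block <- full$person_id == blk$person_id
  # blocking only restricts the candidate pool; where the full winner lies
  # inside the block the two must coincide
  winner <- reg$persons[match(full$person_id, reg$persons$person_id), ]
  inside <- (is.na(enc$sex) | is.na(winner$sex) | enc$sex == winner$sex) &
    (is.na(enc$village) | is.na(winner$village) |
       enc$village == winner$village)
  expect_true(all(agree_on_block[inside]))
})

test_that("nearest-rank percentile thresholds resolve as specified", {
  ts <- resolve_thresholds(c(-21, 13, 24, 35, 61))
  expect_identical(ts$label, c("minimum", "low", "medium", "high"))
  expect_identical(ts$cutoff[1], -21)
  ts2 <- resolve_thresholds(c(10, 20, 30, 40))
  expect_identical(ts2$cutoff, c(10, 10, 20, 30))
  expect_false(is.unsorted(ts2$cutoff))
  expect_error(resolve_thresholds(numeric(0)), "empty")
})

test_that("threshold filtering is inclusive and monotone", {
  set.seed(5)
  bc <- data.frame(encounter_id = sprintf("E%02d", 1:10),
                   person_id = sprintf("P%02d", 1:10),
                   match_score = c(-3, 0, 2, 2, 5, 7, 8, 11, 11, 15))
  expect_identical(nrow(build_linked_dataset(bc, -Inf)), 10L)
  expect_identical(nrow(build_linked_dataset(bc, 16)), 0L)
  med <- median(bc$match_score)
  kept <- build_linked_dataset(bc, med)
  expect_setequal(kept$encounter_id,
                  bc$encounter_id[bc$match_score >= med])
  sizes <- vapply(sort(unique(bc$match_score)),
                  function(ct) nrow(build_linked_dataset(bc, ct)), integer(1))
  expect_false(is.unsorted(rev(sizes)))
})

test_that("QC flags fire on the four integrity rules and stay silent when clean", {
  reg <- list(persons = data.frame(
    person_id = c("P1", "P2", "P3", "P4"),
    birth_year = c(1960, 1975, 1960, 1965),
    sex = c("M", "M", "F", "M"),
    household_id = c("H1", "H2", "H1", "H3"),
    stringsAsFactors = FALSE),
    episodes = data.frame(
      person_id = c("P1", "P2", "P3", "P4"),
      start_day = c(0, 1460, 100, 200),
      end_day = c(1825, 2190, NA, 300), stringsAsFactors = FALSE))
  class(reg) <- "hdss_registry"
  linked <- data.frame(encounter_id = c("E1", "E1"),
                       person_id = c("P1", "P2"), stringsAsFactors = FALSE)
  fl <- qc_flags(linked, reg)
  expect_setequal(fl$rule, c("birth_year_gap_gt10", "overlapping_residency"))
  # same household + conflicting sex
  linked2 <- data.frame(encounter_id = c("E2", "E2"),
                        person_id = c("P1", "P3"), stringsAsFactors = FALSE)
  fl2 <- qc_flags(linked2, reg)
  expect_true("sex_conflict" %in% fl2$rule)
  expect_true("same_household_multimatch" %in% fl2$rule)
  # a 10-year gap is not strictly greater than 10: no flag
  linked3 <- data.frame(encounter_id = c("E3", "E3", "E4"),
                        person_id = c("P2", "P4", "P1"),
                        stringsAsFactors = FALSE)
  fl3 <- qc_flags(linked3, reg)
  expect_false("birth_year_gap_gt10" %in% fl3$rule)
  expect_identical(nrow(qc_flags(linked3[3, ], reg)), 0L)
})

test_that("u estimation and EM refinement return valid parameters", {
  w <- small_world(seed = 61, n = 500, n_cohort = 80)
  el <- w$encounters[w$encounters$encounter_id %in%
                       w$outcomes$encounter_id, ]
  u <- estimate_u_probabilities(el, w$registry, n_pairs = 800, seed = 1)
  expect_true(all(u > 0 & u < 1))
  # sex agrees for about half of random pairs; village for about 1/7
  expect_lt(abs(u[["sex"]] - 0.5), 0.1)
  pm <- estimate_mu_em(el, w$registry, n_pairs = 500, seed = 2)
  expect_s3_class(pm, "match_params")
  expect_true(all(pm$m > pm$u))
})
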