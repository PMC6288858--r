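test_that("link classification matches enumeration on a toy set", {
  gold <- data.frame(encounter_id = sprintf("E%02d", 1:10),
                     person_id = sprintf("P%02d", 1:10),
                     stringsAsFactors = FALSE)
  # perfect linkage
  cc <- classify_links(gold, gold)
  expect_identical(c(cc$tp, cc$fp, cc$fn), c(10L, 0L, 0L))
  # empty linked dataset
  cc0 <- classify_links(gold, gold[0, ])
  expect_identical(c(cc0$tp, cc0$fp, cc0$fn), c(0L, 0L, 10L))
  # 3 deliberate wrong links, 2 dropped -> (5, 3, 5)
  linked <- gold
  linked$person_id[1:3] <- c("P99", "P98", "P97")
  linked <- linked[1:8, ]
  cc2 <- classify_links(gold, linked)
  expect_identical(c(cc2$tp, cc2$fp, cc2$fn), c(5L, 3L, 5L))
  expect_identical(cc2$tp + cc2$fn, cc2$n_gold)
  bad <- data.frame(encounter_id = "EX", person_id = "P01")
  expect_error(classify_links(gold, bad), "gold universe")
})

test_that("linkage metrics reproduce the published worked examples", {
  m1 <- link_metrics(list(n_gold = 405, tp = 248, fp = 157, fn = 157))
  expect_equal(m1$sensitivity, 248 / 405, tolerance = 1e-12)
  expect_equal(round(m1$ppv, 3), 0.612)
  expect_equal(round(100 * m1$sensitivity), 61)
  expect_equal(round(100 * m1$false_match_rate), 39)
  m2 <- link_metrics(list(n_gold = 405, tp = 95, fp = 11, fn = 310))
  expect_equal(round(m2$ppv, 3), 0.896)
  expect_equal(round(100 * m2$sensitivity), 23)
  expect_equal(round(100 * m2$false_match_rate), 10)
  m3 <- link_metrics(list(n_gold = 405, tp = 405, fp = 0, fn = 0))
  expect_identical(c(m3$sensitivity, m3$ppv, m3$false_match_rate), c(1, 1, 0))
  expect_equal(m1$ppv + m1$false_match_rate, 1, tolerance = 1e-12)
  expect_warning(mna <- link_metrics(list(n_gold = 5, tp = 0, fp = 0, fn = 5)),
                 "undefined")
  expect_true(is.nan(mna$ppv))
})

test_that("standardised differences follow the closed forms", {
  expect_identical(standardized_difference(0.4, 0.4, "binary"), 0)
  expect_equal(standardized_difference(0.5, 0.3, "binary"),
               0.2 / sqrt(0.23), tolerance = 1e-12)
  expect_equal(standardized_difference(0.5, 0.3, "binary"), 0.417,
               tolerance = 1e-3)
  expect_equal(standardized_difference(list(mean = 1, sd = 1),
                                       list(mean = 0, sd = 1),
                                       "continuous"), 1, tolerance = 1e-12)
  # antisymmetry and scale invariance
  expect_equal(standardized_difference(0.5, 0.3, "binary"),
               -standardized_difference(0.3, 0.5, "binary"),
               tolerance = 1e-12)
  k <- 7.3
  expect_equal(standardized_difference(list(mean = 2 * k, sd = 1 * k),
                                       list(mean = 1 * k, sd = 2 * k),
                                       "continuous"),
               standardized_difference(list(mean = 2, sd = 1),
                                       list(mean = 1, sd = 2),
                                       "continuous"), tolerance = 1e-12)
  expect_true(is.nan(standardized_difference(0, 0, "binary")))
})

test_that("balance table flags imbalance against the 0.2/0.5/0.8 anchors", {
  set.seed(3)
  make_grp <- function(p_clinic, n = 200) {
    data.frame(modality = ifelse(seq_len(n) <= round(p_clinic * n),
                                 "clinic", "sero_survey"),
               sex = rep(c("F", "M"), length.out = n),
               only = "x", stringsAsFactors = FALSE)
  }
  tab <- balance_table(make_grp(0.35), make_grp(0.65), make_grp(0.35),
                       c("modality", "sex", "only"))
  row <- tab[tab$variable == "modality" & tab$level == "clinic", ]
  expect_equal(row$smd_true_false, (0.35 - 0.65) /
                 sqrt((0.35 * 0.65 + 0.65 * 0.35) / 2), tolerance = 1e-12)
  expect_equal(abs(row$smd_true_false), 0.3 / sqrt(0.2275), tolerance = 1e-9)
  expect_identical(row$mag_true_false, "moderate")
  expect_identical(row$smd_true_missed, 0)
  # identical groups balance exactly; single-level variable is degenerate
  same <- balance_table(make_grp(0.4), make_grp(0.4), make_grp(0.4),
                        c("modality"))
  expect_true(all(same$smd_true_false == 0))
  only <- tab[tab$variable == "only", ]
  expect_true(is.nan(only$smd_true_false))
  # empty group reported absent
  empt <- balance_table(make_grp(0.4), make_grp(0.4)[0, ], make_grp(0.4),
                        c("modality"))
  expect_true(all(is.na(empt$p_false)))
})

test_that("contingency tests choose chi-square or Fisher appropriately", {
  # registered-by-modality counts from the gold-standard cohort
  r <- contingency_test(rbind(c(42, 221), c(75, 67)))
  expect_identical(r$method, "pearson_chisq")
  expect_lt(r$p_value, 0.0001)
  r2 <- contingency_test(rbind(c(10, 10), c(10, 10)))
  expect_equal(r2$statistic, 0, tolerance = 1e-12)
  expect_equal(r2$p_value, 1, tolerance = 1e-12)
  # sparse 2x2 -> Fisher; oracle = hypergeometric enumeration
  r3 <- contingency_test(rbind(c(5, 0), c(0, 5)))
  expect_identical(r3$method, "fisher_exact")
  enum <- sum(vapply(0:5, function(k) {
    p <- stats::dhyper(k, 5, 5, 5)
    if (p <= stats::dhyper(5, 5, 5, 5) + 1e-12) p else 0
  }, numeric(1)))
  expect_equal(r3$p_value, enum, tolerance = 1e-12)
  expect_equal(r3$p_value, 2 / 252, tolerance = 1e-12)
  expect_error(contingency_test(matrix(0, 2, 2)), "all-zero")
})

test_that("metrics across thresholds conserve counts and are monotone", {
  w <- small_world(seed = 71)
  el <- w$encounters[w$encounters$encounter_id %in%
                       w$outcomes$encounter_id, ]
  gl <- w$gold_links[w$gold_links$encounter_id %in% el$encounter_id, ]
  best <- link_best_candidates(el, w$registry)
  th <- resolve_thresholds(true_match_scores(el, w$registry))
  m <- threshold_metrics(best, gl, th)
  expect_true(all(m$tp + m$fn == nrow(gl)))
  expect_equal(m$ppv + m$false_match_rate, rep(1, 4), tolerance = 1e-12)
  expect_false(is.unsorted(rev(m$n_linked)))
  expect_false(is.unsorted(rev(m$fp)))
  expect_false(is.unsorted(m$fn))
  expect_false(is.unsorted(m$ppv))
  expect_false(is.unsorted(rev(m$sensitivity)))
})
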