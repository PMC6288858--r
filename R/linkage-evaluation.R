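# Evaluation of a linkage run against the gold standard: true/false/missed
# classification, sensitivity / PPV / false-match rate, covariate balance via
# standardised differences, and contingency tests.

#' Classify links against the gold standard
#'
#' A linked pair agreeing with the gold link is a true match (TP); a linked
#' pair naming a different person is a false match (FP); a gold pair absent
#' from the linked dataset — because the encounter was not linked at all or
#' was linked to the wrong person — is a missed match (FN). Consequently
#' `tp + fn = n_gold` always.
#'
#' @param gold_links data frame `(encounter_id, person_id)`; one row per
#'   encounter.
#' @param linked_dataset data frame of retained links `(encounter_id,
#'   person_id)`.
#' @return a `confusion_counts` list: `n_gold`, `tp`, `fp`, `fn`.
#' @export
classify_links <- function(gold_links, linked_dataset) {
  if (anyDuplicated(gold_links$encounter_id))
    stop("gold links must map each encounter to exactly one person")
  unknown <- setdiff(linked_dataset$encounter_id, gold_links$encounter_id)
  if (length(unknown) > 0)
    stop("linked encounters absent from the gold universe: ",
         paste(head(unknown, 3), collapse = ", "))
  gold <- gold_links$person_id[match(linked_dataset$encounter_id,
                                     gold_links$encounter_id)]
  tp <- sum(linked_dataset$person_id == gold)
  fp <- sum(linked_dataset$person_id != gold)
  n_gold <- nrow(gold_links)
  structure(list(n_gold = n_gold, tp = tp, fp = fp, fn = n_gold - tp),
            class = "confusion_counts")
}

#' Linkage-error metrics
#'
#' Sensitivity = TP / gold pairs; PPV = TP / linked records; false-match
#' rate = FP / linked records = 1 - PPV.
#'
#' @param counts a `confusion_counts` (or list with `n_gold`, `tp`, `fp`,
#'   `fn`).
#' @return a `link_metrics` list: `sensitivity`, `ppv`, `false_match_rate`,
#'   `n_linked`. With no linked records PPV and the false-match rate are
#'   `NaN` with a warning.
#' @export
link_metrics <- function(counts) {
  if (counts$n_gold <= 0) stop("link_metrics: n_gold must be positive")
  n_linked <- counts$tp + counts$fp
  if (n_linked == 0) {
    warning("no linked records: PPV undefined")
    ppv <- NaN
  } else ppv <- counts$tp / n_linked
  structure(list(sensitivity = counts$tp / counts$n_gold,
                 ppv = ppv,
                 false_match_rate = 1 - ppv,
                 n_linked = n_linked),
            class = "link_metrics")
}

#' Standardised difference between two groups
#'
#' Scale-free group difference: for a continuous variable
#' `(mean_a - mean_b) / sqrt((sd_a^2 + sd_b^2)/2)`; for a binary variable or
#' a level proportion `(p_a - p_b) / sqrt((p_a(1-p_a) + p_b(1-p_b))/2)`.
#' Values of 0.2, 0.5 and 0.8 are conventionally read as small, moderate and
#' large imbalance. The sign is retained.
#'
#' @param a,b group summaries: for `kind = "binary"` the proportions
#'   `p_a`, `p_b`; for `kind = "continuous"` lists/vectors with `mean` and
#'   `sd`.
#' @param kind `"binary"` or `"continuous"`.
#' @return the standardised difference; `NaN` when the pooled variance is 0.
#' @export
standardized_difference <- function(a, b, kind = c("binary", "continuous")) {
  kind <- match.arg(kind)
  if (kind == "binary") {
    pa <- as.numeric(a); pb <- as.numeric(b)
    v <- (pa * (1 - pa) + pb * (1 - pb)) / 2
    num <- pa - pb
  } else {
    v <- (as.numeric(a[["sd"]])^2 + as.numeric(b[["sd"]])^2) / 2
    num <- as.numeric(a[["mean"]]) - as.numeric(b[["mean"]])
  }
  if (v <= 0) return(NaN)
  num / sqrt(v)
}

smd_magnitude <- function(d) {
  a <- abs(d)
  ifelse(is.na(a), NA_character_,
         ifelse(a >= 0.8, "large",
                ifelse(a >= 0.5, "moderate",
                       ifelse(a >= 0.2, "small", "negligible"))))
}

#' Covariate balance across true, false and missed matches
#'
#' One row per level of each categorical variable (or one row for a
#' numeric variable), with group proportions (or mean/sd) and pairwise
#' standardised differences of true matches versus false and versus missed
#' matches, flagged against the 0.2 / 0.5 / 0.8 anchors.
#'
#' @param true_set,false_set,missed_set data frames of records in each
#'   class; an empty class yields `NA` columns.
#' @param variables character vector of column names to compare.
#' @return data frame with columns `variable`, `level`, `p_true`, `p_false`,
#'   `p_missed`, `smd_true_false`, `smd_true_missed`, and magnitude flags.
#' @export
balance_table <- function(true_set, false_set, missed_set, variables) {
  rows <- list()
  grp <- list(true = true_set, false = false_set, missed = missed_set)
  for (v in variables) {
    x <- true_set[[v]]
    if (is.numeric(x) && !is.integer(x) && length(unique(x)) > 8) {
      summ <- lapply(grp, function(g)
        if (nrow(g) == 0) list(mean = NA, sd = NA)
        else list(mean = mean(g[[v]], na.rm = TRUE),
                  sd = sd(g[[v]], na.rm = TRUE)))
      d_tf <- if (nrow(false_set) == 0) NA else
        standardized_difference(summ$true, summ$false, "continuous")
      d_tm <- if (nrow(missed_set) == 0) NA else
        standardized_difference(summ$true, summ$missed, "continuous")
      rows[[length(rows) + 1]] <- data.frame(
        variable = v, level = NA_character_,
        p_true = summ$true$mean, p_false = summ$false$mean,
        p_missed = summ$missed$mean,
        smd_true_false = d_tf, smd_true_missed = d_tm,
        stringsAsFactors = FALSE)
    } else {
      levs <- sort(unique(as.character(
        c(true_set[[v]], false_set[[v]], missed_set[[v]]))))
      for (lv in levs) {
        p <- vapply(grp, function(g)
          if (nrow(g) == 0) NA_real_
          else mean(as.character(g[[v]]) == lv, na.rm = TRUE), numeric(1))
        d_tf <- if (is.na(p[["false"]])) NA else
          standardized_difference(p[["true"]], p[["false"]], "binary")
        d_tm <- if (is.na(p[["missed"]])) NA else
          standardized_difference(p[["true"]], p[["missed"]], "binary")
        rows[[length(rows) + 1]] <- data.frame(
          variable = v, level = lv,
          p_true = p[["true"]], p_false = p[["false"]],
          p_missed = p[["missed"]],
          smd_true_false = d_tf, smd_true_missed = d_tm,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  out$mag_true_false <- smd_magnitude(out$smd_true_false)
  out$mag_true_missed <- smd_magnitude(out$smd_true_missed)
  out
}

#' Contingency-table test of association
#'
#' Pearson chi-square without continuity correction for r x c tables; for a
#' 2 x 2 table with any expected cell below 5, Fisher's exact test
#' (two-sided) instead.
#'
#' @param table matrix of nonnegative integer counts.
#' @return list: `method`, `statistic` (`NA` for Fisher), `p_value`,
#'   `expected`.
#' @export
contingency_test <- function(table) {
  table <- as.matrix(table)
  if (any(table < 0)) stop("contingency_test: counts must be nonnegative")
  if (sum(table) == 0) stop("contingency_test: all-zero table")
  expected <- outer(rowSums(table), colSums(table)) / sum(table)
  if (all(dim(table) == c(2, 2)) && any(expected < 5)) {
    ft <- fisher.test(table)
    return(list(method = "fisher_exact", statistic = NA_real_,
                p_value = ft$p.value, expected = expected))
  }
  ct <- suppressWarnings(chisq.test(table, correct = FALSE))
  list(method = "pearson_chisq", statistic = unname(ct$statistic),
       p_value = ct$p.value, expected = expected)
}

#' Error metrics across match-score thresholds
#'
#' Builds the linked dataset at each threshold, classifies links against the
#' gold standard and assembles one metrics row per threshold.
#'
#' @param best_candidates output of [link_best_candidates()].
#' @param gold_links data frame `(encounter_id, person_id)`.
#' @param thresholds a `threshold_set` from [resolve_thresholds()].
#' @return data frame: `label`, `cutoff`, `n_linked`, `tp`, `fp`, `fn`,
#'   `sensitivity`, `ppv`, `false_match_rate`.
#' @export
threshold_metrics <- function(best_candidates, gold_links, thresholds) {
  rows <- lapply(seq_len(nrow(thresholds)), function(i) {
    linked <- build_linked_dataset(best_candidates, thresholds$cutoff[i])
    cc <- classify_links(gold_links, linked)
    lm_ <- link_metrics(cc)
    data.frame(label = thresholds$label[i], cutoff = thresholds$cutoff[i],
               n_linked = lm_$n_linked, tp = cc$tp, fp = cc$fp, fn = cc$fn,
               sensitivity = lm_$sensitivity, ppv = lm_$ppv,
               false_match_rate = lm_$false_match_rate,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
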