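# Eligibility filtering, censored time-to-registration construction, Cox
# model fits, and the cross-threshold bias/precision experiment.

#' Apply cohort eligibility rules
#'
#' Retains first positive diagnoses of HDSS residents aged 15 or older:
#' excludes encounters under 15 at diagnosis, repeat testers (evidence of a
#' prior positive test or prior care registration), and non-residents.
#'
#' @param encounters encounter data frame with `age_at_encounter`,
#'   `prior_positive_flag` and `resident` columns.
#' @return the eligible subset, with an `exclusions` attribute giving counts
#'   by reason (first matching reason, in the order under_15 /
#'   repeat_tester / non_resident).
#' @export
apply_eligibility <- function(encounters) {
  u15 <- !is.na(encounters$age_at_encounter) & encounters$age_at_encounter < 15
  rep_t <- !u15 & encounters$prior_positive_flag
  nonres <- !u15 & !rep_t & !encounters$resident
  keep <- !(u15 | rep_t | nonres)
  out <- encounters[keep, , drop = FALSE]
  attr(out, "exclusions") <- c(under_15 = sum(u15),
                               repeat_tester = sum(rep_t),
                               non_resident = sum(nonres))
  out
}

#' Censored time from diagnosis to care registration
#'
#' Time runs from diagnosis to the earliest of care registration, death, or
#' `admin_days` after diagnosis; the event indicator is 1 only when
#' registration comes first. Same-day registration is set to 0.5 days so
#' times stay positive for the partial likelihood.
#'
#' @param diagnosis_date,registration_date,death_date numeric dates (days);
#'   `NA` = did not occur. Vectors are recycled to a common length.
#' @param admin_days administrative censoring horizon (default 90).
#' @return data frame with `time_days` and `event`.
#' @export
build_time_to_event <- function(diagnosis_date, registration_date = NA,
                                death_date = NA, admin_days = 90) {
  n <- max(length(diagnosis_date), length(registration_date),
           length(death_date))
  dg <- rep_len(as.numeric(diagnosis_date), n)
  rg <- rep_len(as.numeric(registration_date), n)
  dt <- rep_len(as.numeric(death_date), n)
  if (any(!is.na(rg) & rg < dg))
    stop("registration before diagnosis; such records should have been ",
         "excluded as repeat testers")
  if (any(!is.na(dt) & dt < dg))
    stop("death before diagnosis")
  t_reg <- ifelse(is.na(rg), Inf, rg - dg)
  t_death <- ifelse(is.na(dt), Inf, dt - dg)
  time <- pmin(t_reg, t_death, admin_days)
  event <- as.integer(is.finite(t_reg) & t_reg <= t_death &
                        t_reg <= admin_days)
  time[event == 1 & time == 0] <- 0.5
  data.frame(time_days = time, event = event)
}

#' Cox proportional-hazards fit of the modality effect
#'
#' Fits `Surv(time_days, event) ~ modality + covariates` by partial
#' likelihood with Efron tie handling, and extracts the clinic-vs-sero-survey
#' coefficient. Reference levels: sero-survey, 15-29, female, rural, no
#' paved road, <1 km.
#'
#' @param cohort data frame with `time_days`, `event`, `modality` and the
#'   covariate columns.
#' @param covariates adjuster columns entered as indicator contrasts.
#'   Default: the five-adjuster set (age group, sex, rurality, paved road,
#'   distance band). Use `character(0)` for an unadjusted fit.
#' @return a `cox_fit` list: `beta`, `se`, `wald_chisq`, `p_value`, `hr`,
#'   `ci_low`, `ci_high`, `n`, `n_events`, and the underlying `fit`.
#' @export
fit_cox <- function(cohort,
                    covariates = c("age_group", "sex", "rurality",
                                   "paved_road", "distance_band")) {
  ev_by_mod <- tapply(cohort$event, cohort$modality, sum)
  if (length(ev_by_mod) < 2 || any(is.na(ev_by_mod)) || any(ev_by_mod < 1))
    stop("fit_cox: need at least one event in each modality group")
  d <- cohort
  d$modality <- factor(d$modality, levels = MODALITY_LEVELS)
  if ("age_group" %in% covariates)
    d$age_group <- factor(d$age_group, levels = AGE_LEVELS)
  if ("sex" %in% covariates) d$sex <- factor(d$sex, levels = c("F", "M"))
  if ("rurality" %in% covariates)
    d$rurality <- factor(d$rurality, levels = RURALITY_LEVELS)
  if ("distance_band" %in% covariates)
    d$distance_band <- factor(d$distance_band, levels = DIST_LEVELS)
  # drop covariates with a single observed level (small thresholded samples)
  covariates <- covariates[vapply(covariates, function(v)
    length(unique(d[[v]][!is.na(d[[v]])])) > 1, logical(1))]
  fml <- stats::reformulate(c("modality", covariates),
                            response = "survival::Surv(time_days, event)")
  # sparse covariate levels in small thresholded samples can fail to
  # converge; only the modality term is extracted and it is checked below
  fit <- suppressWarnings(survival::coxph(fml, data = d, ties = "efron"))
  beta <- unname(stats::coef(fit)["modalityclinic"])
  se <- sqrt(diag(fit$var))[[which(names(stats::coef(fit)) ==
                                     "modalityclinic")]]
  if (!is.finite(beta) || !is.finite(se))
    stop("fit_cox: non-convergence or separation on the modality term")
  wald <- (beta / se)^2
  structure(list(beta = beta, se = se, wald_chisq = wald,
                 p_value = stats::pchisq(wald, 1, lower.tail = FALSE),
                 hr = exp(beta),
                 ci_low = exp(beta - 1.96 * se),
                 ci_high = exp(beta + 1.96 * se),
                 n = nrow(d), n_events = sum(d$event),
                 fit = fit),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, digits = 3, ...) {
  cat(sprintf("<cox_fit> n=%d events=%d  beta=%.*f se=%.*f  HR=%.*f (%.*f, %.*f)\n",
              x$n, x$n_events, digits, x$beta, digits, x$se, digits, x$hr,
              digits, x$ci_low, digits, x$ci_high))
  invisible(x)
}

# Analysis rows an analyst of the linked file would assemble: exposure and
# diagnosis date from the encounter; outcome history and covariates from the
# linked registry person. A correctly linked encounter recovers its true
# outcome row; a falsely linked one inherits the wrong person's (latent
# background) registration/death history.
assemble_linked_analysis <- function(linked, world) {
  persons <- world$registry$persons
  oc <- world$outcomes
  oi <- match(linked$encounter_id, oc$encounter_id)
  pi <- match(linked$person_id, persons$person_id)
  gold <- world$gold_links$person_id[match(linked$encounter_id,
                                           world$gold_links$encounter_id)]
  correct <- linked$person_id == gold

  out <- data.frame(encounter_id = linked$encounter_id,
                    person_id = linked$person_id,
                    modality = oc$modality[oi],
                    stringsAsFactors = FALSE)
  # covariates as recorded on the linked HDSS record
  diag_day <- oc$diagnosis_day[oi]
  age <- floor(EPOCH_YEAR + diag_day / 365.25) - persons$birth_year[pi]
  out$age_group <- as.character(age_group_of(age))
  out$age_group[is.na(out$age_group)] <- oc$age_group[oi][is.na(out$age_group)]
  out$sex <- persons$sex[pi]
  out$rurality <- persons$rurality[pi]
  out$paved_road <- persons$paved_road[pi]
  out$distance_band <- persons$distance_band[pi]

  li <- match(linked$person_id, world$latent$person_id)
  horizon <- world$outcome_config$admin_censor_days
  bg <- build_time_to_event(rep(0, nrow(linked)),
                            ifelse(world$latent$bg_reg_offset[li] <=
                                     world$latent$bg_death_offset[li],
                                   world$latent$bg_reg_offset[li], NA),
                            ifelse(world$latent$bg_death_offset[li] <
                                     world$latent$bg_reg_offset[li],
                                   world$latent$bg_death_offset[li], NA),
                            admin_days = horizon)
  out$time_days <- ifelse(correct, oc$time_days[oi], bg$time_days)
  out$event <- ifelse(correct, oc$event[oi], bg$event)
  out$true_match <- correct
  out
}

#' Cross-threshold bias and precision experiment
#'
#' Runs the full pipeline on one synthetic world: links eligible encounters
#' to the registry, resolves percentile thresholds on the true-match score
#' distribution, builds the four thresholded analytic datasets plus the
#' gold-standard dataset, fits the Cox model on each, and summarises bias
#' (attenuation of the modality coefficient), precision (SE ratio), and the
#' least-squares R-squared of SE against missed-match count across
#' thresholds.
#'
#' @param world a `linkerr_world` from [make_world()].
#' @param params a [match_params()].
#' @param percentiles threshold percentiles (default 0/25/50/75).
#' @param covariates adjuster set passed to [fit_cox()].
#' @return a `threshold_report` list: `table` (one row per threshold plus
#'   gold: linkage metrics and Cox estimates), `r_squared`, `r_squared_p`,
#'   `thresholds`, `best_candidates`.
#' @export
threshold_experiment <- function(world, params = match_params(),
                                 percentiles = c(0, 25, 50, 75),
                                 covariates = c("age_group", "sex",
                                                "rurality", "paved_road",
                                                "distance_band")) {
  eligible <- apply_eligibility(world$encounters)
  elig <- eligible[eligible$encounter_id %in% world$outcomes$encounter_id, ,
                   drop = FALSE]
  gold_links <- world$gold_links[world$gold_links$encounter_id %in%
                                   elig$encounter_id, , drop = FALSE]

  best <- link_best_candidates(elig, world$registry, params)
  ts <- true_match_scores(elig, world$registry, params)
  thresholds <- resolve_thresholds(ts, percentiles)
  metrics <- threshold_metrics(best, gold_links, thresholds)

  gold_fit <- fit_cox(world$outcomes, covariates)
  fit_row <- function(fit) {
    if (is.null(fit)) return(data.frame(beta = NA, se = NA, wald_chisq = NA,
                                        p_value = NA, hr = NA, ci_low = NA,
                                        ci_high = NA, n_events = NA))
    data.frame(beta = fit$beta, se = fit$se, wald_chisq = fit$wald_chisq,
               p_value = fit$p_value, hr = fit$hr, ci_low = fit$ci_low,
               ci_high = fit$ci_high, n_events = fit$n_events)
  }
  rows <- list(cbind(data.frame(label = "gold", cutoff = NA,
                                n_linked = nrow(world$outcomes), tp = NA,
                                fp = NA, fn = NA, sensitivity = NA, ppv = NA,
                                false_match_rate = NA),
                     fit_row(gold_fit)))
  for (i in seq_len(nrow(thresholds))) {
    linked <- build_linked_dataset(best, thresholds$cutoff[i])
    dat <- assemble_linked_analysis(linked, world)
    fit <- tryCatch(fit_cox(dat, covariates), error = function(e) NULL)
    rows[[i + 1]] <- cbind(metrics[i, , drop = FALSE], fit_row(fit))
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  tab$attenuation <- tab$beta - tab$beta[1]
  tab$se_ratio <- tab$se / tab$se[1]

  thr <- tab[-1, , drop = FALSE]
  ok <- is.finite(thr$se)
  reg <- if (sum(ok) >= 3) se_missed_r_squared(thr$fn[ok], thr$se[ok])
         else list(r_squared = NA_real_, p_value = NA_real_)
  structure(list(table = tab, r_squared = reg$r_squared,
                 r_squared_p = reg$p_value, thresholds = thresholds,
                 best_candidates = best),
            class = "threshold_report")
}

#' @export
print.threshold_report <- function(x, ...) {
  cat("<threshold_report>\n")
  print(x$table[, c("label", "n_linked", "ppv", "beta", "se", "hr")],
        digits = 3)
  cat(sprintf("R^2(SE ~ missed) = %.3f (p = %.3g)\n", x$r_squared,
              x$r_squared_p))
  invisible(x)
}

#' R-squared of precision loss against missed matches
#'
#' Ordinary least-squares regression of the modality-coefficient standard
#' error on the missed-match count across thresholds; p-value from the F
#' test.
#'
#' @param missed missed-match counts (one per threshold).
#' @param se standard errors (same length).
#' @return list with `r_squared`, `p_value`, `slope`.
#' @export
se_missed_r_squared <- function(missed, se) {
  fit <- lm(se ~ missed)
  # collinear 4-point inputs trigger a spurious perfect-fit warning
  s <- suppressWarnings(summary(fit))
  fstat <- s$fstatistic
  p <- if (is.null(fstat)) NA_real_
       else unname(pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE))
  list(r_squared = unname(s$r.squared), p_value = p,
       slope = unname(stats::coef(fit)[2]))
}
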