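# Fellegi-Sunter probabilistic linkage of encounter records against the
# HDSS registry: Jaro-Winkler name comparison (order-relaxed), log2
# likelihood-ratio field weights, best-candidate selection, percentile
# match-score thresholds, and data-integrity QC flags.

FS_FIELDS <- c("name", "sex", "birth_year", "birth_month", "birth_day",
               "village", "sub_village", "hh_member_name", "tcl_name")

#' Fellegi-Sunter matching parameters
#'
#' `m` is the probability a field agrees on a true match, `u` the probability
#' it agrees on a non-match; the evidence a field contributes is
#' `log2(m/u)` on agreement and `log2((1-m)/(1-u))` on disagreement, and
#' nothing when either side is absent. `m > u` is required for every field.
#' The default `u` values are rough registry-scale agreement rates; for
#' experiments estimate them from data with [estimate_u_probabilities()] or
#' refine both with [estimate_mu_em()].
#'
#' @param m,u named numeric vectors over the nine comparison fields
#'   (`name`, `sex`, `birth_year`, `birth_month`, `birth_day`, `village`,
#'   `sub_village`, `hh_member_name`, `tcl_name`).
#' @param jw_agreement_threshold minimum Jaro-Winkler similarity counted as
#'   name agreement.
#' @param winkler_prefix_scale,winkler_max_prefix Winkler prefix-boost
#'   parameters.
#' @return a `match_params` list.
#' @export
match_params <- function(m = c(name = 0.90, sex = 0.95, birth_year = 0.90,
                               birth_month = 0.90, birth_day = 0.90,
                               village = 0.95, sub_village = 0.95,
                               hh_member_name = 0.90, tcl_name = 0.90),
                         u = c(name = 0.05, sex = 0.50, birth_year = 0.02,
                               birth_month = 0.083, birth_day = 0.036,
                               village = 0.15, sub_village = 0.04,
                               hh_member_name = 0.05, tcl_name = 0.05),
                         jw_agreement_threshold = 0.85,
                         winkler_prefix_scale = 0.1,
                         winkler_max_prefix = 4L) {
  m <- m[FS_FIELDS]; u <- u[FS_FIELDS]
  if (anyNA(m) || anyNA(u))
    stop("match_params: 'm' and 'u' must name all fields: ",
         paste(FS_FIELDS, collapse = ", "))
  if (any(m <= u))
    stop("match_params: m must exceed u for every field ",
         "(agreement must be evidence for a match); offending: ",
         paste(FS_FIELDS[m <= u], collapse = ", "))
  if (any(u <= 0) || any(m >= 1))
    stop("match_params: require 0 < u < m < 1")
  if (jw_agreement_threshold < 0 || jw_agreement_threshold > 1)
    stop("match_params: 'jw_agreement_threshold' must be in [0, 1]")
  structure(list(m = m, u = u,
                 jw_agreement_threshold = jw_agreement_threshold,
                 winkler_prefix_scale = winkler_prefix_scale,
                 winkler_max_prefix = as.integer(winkler_max_prefix)),
            class = "match_params")
}

#' Jaro-Winkler string similarity
#'
#' Standard Jaro similarity (matching window `floor(max(|a|,|b|)/2) - 1`,
#' transpositions counted half each) with the Winkler boost for a shared
#' prefix of up to `max_prefix` characters. Symmetric; 1 iff the strings are
#' identical and nonempty; 0 when either string is empty or no characters
#' match.
#'
#' @param a,b character vectors (recycled to a common length).
#' @param prefix_scale Winkler prefix scale (default 0.1).
#' @param max_prefix maximum prefix length receiving the boost (default 4).
#' @return numeric vector of similarities in `[0, 1]`; `NA` where either
#'   input is `NA`.
#' @export
jaro_winkler <- function(a, b, prefix_scale = 0.1, max_prefix = 4L) {
  .jw_cpp(as.character(a), as.character(b), prefix_scale,
          as.integer(max_prefix))
}

#' Order-relaxed name-field comparison
#'
#' Compares two lists of recorded names by the maximum Jaro-Winkler
#' similarity over all cross pairs, so the order in which names were written
#' down is irrelevant. The field is `missing` when either list holds no
#' name, `agree` when the best similarity reaches the agreement threshold,
#' else `disagree`.
#'
#' @param names_a,names_b character vectors of 0-3 names (`NA`s and empty
#'   strings are dropped).
#' @param params a [match_params()].
#' @return list with `outcome` (`"agree"`, `"disagree"` or `"missing"`) and
#'   `best_similarity` (`NA` when missing).
#' @export
name_field_agreement <- function(names_a, names_b, params = match_params()) {
  names_a <- names_a[!is.na(names_a) & nzchar(names_a)]
  names_b <- names_b[!is.na(names_b) & nzchar(names_b)]
  if (length(names_a) == 0 || length(names_b) == 0)
    return(list(outcome = "missing", best_similarity = NA_real_))
  sims <- outer(names_a, names_b,
                function(x, y) jaro_winkler(x, y, params$winkler_prefix_scale,
                                            params$winkler_max_prefix))
  best <- max(sims)
  list(outcome = if (best >= params$jw_agreement_threshold) "agree"
       else "disagree",
       best_similarity = best)
}

#' Fellegi-Sunter field weight
#'
#' @param outcome `"agree"` or `"disagree"` (missing fields contribute no
#'   weight and are handled by the caller).
#' @param m,u the field's match/non-match agreement probabilities,
#'   `0 < u < m < 1`.
#' @return `log2(m/u)` on agreement (positive), `log2((1-m)/(1-u))` on
#'   disagreement (negative).
#' @export
field_weight <- function(outcome, m, u) {
  if (!(m > u)) stop("field_weight: require m > u")
  if (u <= 0 || m >= 1) stop("field_weight: require 0 < u < m < 1")
  outcome <- match.arg(outcome, c("agree", "disagree"))
  if (outcome == "agree") log2(m / u) else log2((1 - m) / (1 - u))
}

# Collect the up-to-three recorded names of a name-type field from a record.
record_names <- function(rec, field) {
  cols <- switch(field,
                 name = c("name_1", "name_2", "name_3"),
                 hh_member_name = c("hh_member_name_1", "hh_member_name_2",
                                    "hh_member_name_3"),
                 tcl_name = c("tcl_name_1", "tcl_name_2", "tcl_name_3"))
  cols <- intersect(cols, names(rec))
  as.character(unlist(rec[cols], use.names = FALSE))
}

#' Score one encounter-person pair
#'
#' Compares the nine matching fields: the three name-type fields (personal,
#' household-member and ten-cell-leader names) with the order-relaxed
#' Jaro-Winkler rule, the rest by exact equality; sums Fellegi-Sunter
#' weights over non-missing fields.
#'
#' @param encounter one encounter record (single-row data frame or list).
#' @param person one registry person (single-row data frame or list).
#' @param params a [match_params()].
#' @return a `candidate_pair` list: `encounter_id`, `person_id`, per-field
#'   `outcomes`, and `match_score`.
#' @export
score_pair <- function(encounter, person, params = match_params()) {
  outcomes <- setNames(character(length(FS_FIELDS)), FS_FIELDS)
  score <- 0
  for (f in c("name", "hh_member_name", "tcl_name")) {
    r <- name_field_agreement(record_names(encounter, f),
                              record_names(person, f), params)
    outcomes[f] <- r$outcome
    if (r$outcome != "missing")
      score <- score + field_weight(r$outcome, params$m[[f]], params$u[[f]])
  }
  for (f in c("sex", "birth_year", "birth_month", "birth_day", "village",
              "sub_village")) {
    ev <- encounter[[f]]; pv <- person[[f]]
    if (is.null(ev) || is.null(pv) || is.na(ev) || is.na(pv)) {
      outcomes[f] <- "missing"
    } else {
      outcomes[f] <- if (as.character(ev) == as.character(pv)) "agree"
                     else "disagree"
      score <- score + field_weight(outcomes[f], params$m[[f]], params$u[[f]])
    }
  }
  structure(list(encounter_id = encounter[["encounter_id"]],
                 person_id = person[["person_id"]],
                 outcomes = outcomes, match_score = score),
            class = "candidate_pair")
}

# Character matrices the C++ scorer consumes.
as_name_matrix <- function(df, cols) {
  cols <- intersect(cols, names(df))
  m <- as.matrix(df[, cols, drop = FALSE])
  storage.mode(m) <- "character"
  m[!is.na(m) & m == ""] <- NA
  m
}

as_exact_matrix <- function(df) {
  cols <- c("sex", "birth_year", "birth_month", "birth_day", "village",
            "sub_village")
  m <- sapply(cols, function(cl)
    if (cl %in% names(df)) as.character(df[[cl]])
    else rep(NA_character_, nrow(df)))
  matrix(m, nrow = nrow(df), dimnames = list(NULL, cols))
}

#' Select the best-scoring registry candidate for every encounter
#'
#' Scores each encounter against every registry person (full cross product;
#' optionally blocked on sex and village) and keeps the highest-scoring
#' person per encounter. Many encounters may select the same person; no
#' one-to-one constraint is imposed. Ties on score are broken by fewest
#' disagreeing fields, then lowest `person_id`, and are flagged.
#'
#' @param encounters encounter data frame.
#' @param registry an `hdss_registry` or its `persons` data frame.
#' @param params a [match_params()].
#' @param block if `TRUE`, only persons agreeing (or missing) on sex and
#'   village are scored for each encounter.
#' @return data frame with one row per encounter: `encounter_id`,
#'   `person_id`, `match_score`, `n_disagree`, `tie`.
#' @export
link_best_candidates <- function(encounters, registry,
                                 params = match_params(), block = FALSE) {
  persons <- if (inherits(registry, "hdss_registry")) registry$persons
             else registry
  if (is.null(persons) || nrow(persons) == 0) stop("registry is empty")
  persons <- persons[order(persons$person_id), , drop = FALSE]

  run <- function(enc, per) {
    res <- .link_best_cpp(
      as_name_matrix(enc, c("name_1", "name_2", "name_3")),
      as_name_matrix(enc, c("hh_member_name_1", "hh_member_name_2",
                            "hh_member_name_3")),
      as_name_matrix(enc, c("tcl_name_1", "tcl_name_2", "tcl_name_3")),
      as_exact_matrix(enc),
      as_name_matrix(per, c("name_1", "name_2", "name_3")),
      as_name_matrix(per, c("hh_member_name_1", "hh_member_name_2",
                            "hh_member_name_3")),
      as_name_matrix(per, c("tcl_name_1", "tcl_name_2", "tcl_name_3")),
      as_exact_matrix(per),
      unname(params$m[FS_FIELDS]), unname(params$u[FS_FIELDS]),
      params$jw_agreement_threshold, params$winkler_prefix_scale,
      params$winkler_max_prefix)
    data.frame(encounter_id = enc$encounter_id,
               person_id = per$person_id[res$person_idx],
               match_score = res$match_score,
               n_disagree = res$n_disagree,
               tie = res$tie, stringsAsFactors = FALSE)
  }

  if (!block) return(run(encounters, persons))

  out <- vector("list", nrow(encounters))
  for (i in seq_len(nrow(encounters))) {
    e <- encounters[i, , drop = FALSE]
    keep <- rep(TRUE, nrow(persons))
    if (!is.na(e$sex)) keep <- keep & (is.na(persons$sex) | persons$sex == e$sex)
    if (!is.na(e$village))
      keep <- keep & (is.na(persons$village) | persons$village == e$village)
    blockp <- persons[keep, , drop = FALSE]
    if (nrow(blockp) == 0) blockp <- persons
    out[[i]] <- run(e, blockp)
  }
  do.call(rbind, out)
}

#' Score the gold-standard (true) pairs
#'
#' Computes the match score of each encounter against its gold person; the
#' distribution of these true-match scores is what the percentile thresholds
#' are anchored on.
#'
#' @param encounters encounter data frame with `gold_person_id` (or supply
#'   `gold_links`).
#' @param registry an `hdss_registry` or persons data frame.
#' @param params a [match_params()].
#' @param gold_links optional data frame `(encounter_id, person_id)`.
#' @return numeric vector of true-pair scores, one per encounter.
#' @export
true_match_scores <- function(encounters, registry, params = match_params(),
                              gold_links = NULL) {
  persons <- if (inherits(registry, "hdss_registry")) registry$persons
             else registry
  gold <- if (is.null(gold_links)) encounters$gold_person_id
          else gold_links$person_id[match(encounters$encounter_id,
                                          gold_links$encounter_id)]
  gi <- match(gold, persons$person_id)
  if (anyNA(gi)) stop("gold person missing from registry")
  per <- persons[gi, , drop = FALSE]
  .score_aligned_cpp(
    as_name_matrix(encounters, c("name_1", "name_2", "name_3")),
    as_name_matrix(encounters, c("hh_member_name_1", "hh_member_name_2",
                                 "hh_member_name_3")),
    as_name_matrix(encounters, c("tcl_name_1", "tcl_name_2", "tcl_name_3")),
    as_exact_matrix(encounters),
    as_name_matrix(per, c("name_1", "name_2", "name_3")),
    as_name_matrix(per, c("hh_member_name_1", "hh_member_name_2",
                          "hh_member_name_3")),
    as_name_matrix(per, c("tcl_name_1", "tcl_name_2", "tcl_name_3")),
    as_exact_matrix(per),
    unname(params$m[FS_FIELDS]), unname(params$u[FS_FIELDS]),
    params$jw_agreement_threshold, params$winkler_prefix_scale,
    params$winkler_max_prefix)
}

#' Percentile-based match-score thresholds
#'
#' Resolves the labelled thresholds (minimum/low/medium/high) as nearest-rank
#' percentiles of the true-match score distribution: percentile 0 is the
#' minimum score; percentile p > 0 is the `ceiling(p/100 * n)`-th order
#' statistic.
#'
#' @param scores numeric vector of true-match scores.
#' @param percentiles percentiles defining the thresholds (default
#'   0/25/50/75).
#' @param labels threshold labels.
#' @return a `threshold_set` data frame: `label`, `percentile`, `cutoff`.
#' @export
resolve_thresholds <- function(scores, percentiles = c(0, 25, 50, 75),
                               labels = c("minimum", "low", "medium",
                                          "high")) {
  if (length(scores) == 0) stop("resolve_thresholds: empty score list")
  stopifnot(length(percentiles) == length(labels))
  s <- sort(scores)
  n <- length(s)
  cutoff <- vapply(percentiles, function(p) {
    if (p <= 0) s[1] else s[max(1L, ceiling(p / 100 * n))]
  }, numeric(1))
  if (is.unsorted(cutoff)) stop("resolved cutoffs must be nondecreasing")
  structure(data.frame(label = labels, percentile = percentiles,
                       cutoff = cutoff, stringsAsFactors = FALSE),
            class = c("threshold_set", "data.frame"))
}

#' Retain best candidates at or above a score cutoff
#'
#' @param best_candidates output of [link_best_candidates()].
#' @param cutoff score threshold; the comparison is inclusive (`>=`), so the
#'   minimum true-score threshold retains every best candidate.
#' @return the linked dataset (subset of `best_candidates`).
#' @export
build_linked_dataset <- function(best_candidates, cutoff) {
  best_candidates[best_candidates$match_score >= cutoff, , drop = FALSE]
}

#' Data-integrity flags on a linked dataset
#'
#' Reproduces the back-end integrity checks: when one encounter is linked to
#' several registry persons, flags pairs of linked records with an absolute
#' birth-year gap greater than 10 years, conflicting sex, shared household,
#' or overlapping household residency episodes.
#'
#' @param linked data frame of links `(encounter_id, person_id)`, possibly
#'   several persons per encounter.
#' @param registry an `hdss_registry` (episodes are needed for the
#'   residency rule).
#' @return data frame of flags: `encounter_id`, `rule`, `detail`.
#' @export
qc_flags <- function(linked, registry) {
  persons <- registry$persons
  episodes <- registry$episodes
  flags <- list()
  add <- function(eid, rule, detail)
    flags[[length(flags) + 1]] <<- data.frame(encounter_id = eid, rule = rule,
                                              detail = detail,
                                              stringsAsFactors = FALSE)
  overlap <- function(p1, p2) {
    e1 <- episodes[episodes$person_id == p1, , drop = FALSE]
    e2 <- episodes[episodes$person_id == p2, , drop = FALSE]
    for (i in seq_len(nrow(e1))) for (j in seq_len(nrow(e2))) {
      s1 <- e1$start_day[i]; d1 <- e1$end_day[i]
      s2 <- e2$start_day[j]; d2 <- e2$end_day[j]
      if (is.na(d1)) d1 <- Inf
      if (is.na(d2)) d2 <- Inf
      if (s1 < d2 && s2 < d1) return(TRUE)
    }
    FALSE
  }
  for (eid in unique(linked$encounter_id)) {
    pid <- unique(linked$person_id[linked$encounter_id == eid])
    if (length(pid) < 2) next
    pp <- persons[match(pid, persons$person_id), , drop = FALSE]
    cmb <- utils::combn(seq_along(pid), 2)
    for (k in seq_len(ncol(cmb))) {
      i <- cmb[1, k]; j <- cmb[2, k]
      gap <- abs(pp$birth_year[i] - pp$birth_year[j])
      if (!is.na(gap) && gap > 10)
        add(eid, "birth_year_gap_gt10",
            paste0(pp$person_id[i], "/", pp$person_id[j], " gap ", gap))
      if (!is.na(pp$sex[i]) && !is.na(pp$sex[j]) && pp$sex[i] != pp$sex[j])
        add(eid, "sex_conflict",
            paste0(pp$person_id[i], "/", pp$person_id[j]))
      if (!is.na(pp$household_id[i]) &&
          identical(pp$household_id[i], pp$household_id[j]))
        add(eid, "same_household_multimatch", pp$household_id[i])
      if (overlap(pp$person_id[i], pp$person_id[j]))
        add(eid, "overlapping_residency",
            paste0(pp$person_id[i], "/", pp$person_id[j]))
    }
  }
  if (length(flags) == 0)
    return(data.frame(encounter_id = character(0), rule = character(0),
                      detail = character(0), stringsAsFactors = FALSE))
  do.call(rbind, flags)
}

#' Estimate u-probabilities from random record pairs
#'
#' The probability each field agrees between records of two different
#' people, estimated by sampling random encounter-person pairs (discarding
#' the rare gold pairs). Standard practice when no training labels exist.
#'
#' @param encounters encounter data frame.
#' @param registry an `hdss_registry` or persons data frame.
#' @param params a [match_params()] (supplies the name-agreement rule).
#' @param n_pairs number of random pairs to sample.
#' @param seed RNG seed.
#' @param floor_u lower bound kept away from 0 so weights stay finite.
#' @return named numeric vector of u estimates over the nine fields.
#' @export
estimate_u_probabilities <- function(encounters, registry,
                                     params = match_params(),
                                     n_pairs = 5000, seed = 1L,
                                     floor_u = 0.002) {
  persons <- if (inherits(registry, "hdss_registry")) registry$persons
             else registry
  set.seed(seed)
  ei <- sample.int(nrow(encounters), n_pairs, replace = TRUE)
  pi <- sample.int(nrow(persons), n_pairs, replace = TRUE)
  if ("gold_person_id" %in% names(encounters)) {
    keep <- encounters$gold_person_id[ei] != persons$person_id[pi]
    ei <- ei[keep]; pi <- pi[keep]
  }
  agree <- matrix(NA, length(ei), length(FS_FIELDS),
                  dimnames = list(NULL, FS_FIELDS))
  for (k in seq_along(ei)) {
    cp <- score_pair(encounters[ei[k], , drop = FALSE],
                     persons[pi[k], , drop = FALSE], params)
    agree[k, ] <- ifelse(cp$outcomes == "missing", NA,
                         cp$outcomes == "agree")
  }
  u <- colMeans(agree, na.rm = TRUE)
  pmin(pmax(u, floor_u), 0.98)
}

#' EM refinement of m- and u-probabilities
#'
#' Two-class latent mixture EM over per-field binary agreement outcomes of
#' sampled record pairs (missing comparisons dropped from a pair's
#' likelihood), the classical unsupervised estimator for Fellegi-Sunter
#' parameters. Intended as an optional refinement of the defaults; results
#' are clamped so `m > u` always holds.
#'
#' @inheritParams estimate_u_probabilities
#' @param init a [match_params()] providing starting values.
#' @param prior_match initial mixing proportion of true matches.
#' @param max_iter,tol EM stopping rule.
#' @return a [match_params()] with refined `m`, `u`.
#' @export
estimate_mu_em <- function(encounters, registry, init = match_params(),
                           n_pairs = 2000, seed = 1L, prior_match = 0.01,
                           max_iter = 50, tol = 1e-6) {
  persons <- if (inherits(registry, "hdss_registry")) registry$persons
             else registry
  set.seed(seed)
  # include each encounter's gold pair when known so the match class is
  # represented, plus random pairs
  ei <- sample.int(nrow(encounters), n_pairs, replace = TRUE)
  pi <- sample.int(nrow(persons), n_pairs, replace = TRUE)
  if ("gold_person_id" %in% names(encounters)) {
    gi <- match(encounters$gold_person_id, persons$person_id)
    ei <- c(seq_len(nrow(encounters)), ei)
    pi <- c(gi, pi)
  }
  A <- matrix(NA, length(ei), length(FS_FIELDS),
              dimnames = list(NULL, FS_FIELDS))
  for (k in seq_along(ei)) {
    cp <- score_pair(encounters[ei[k], , drop = FALSE],
                     persons[pi[k], , drop = FALSE], init)
    A[k, ] <- ifelse(cp$outcomes == "missing", NA, cp$outcomes == "agree")
  }
  m <- unname(init$m[FS_FIELDS]); u <- unname(init$u[FS_FIELDS])
  p <- prior_match
  loglik_part <- function(prob) {
    # per-pair log-likelihood under one class, missing fields dropped
    L <- sweep(A, 2, log(prob), `*`) +
      sweep(1 - A, 2, log(1 - prob), `*`)
    rowSums(L, na.rm = TRUE)
  }
  for (it in seq_len(max_iter)) {
    lm_ <- log(p) + loglik_part(m)
    lu_ <- log(1 - p) + loglik_part(u)
    g <- 1 / (1 + exp(lu_ - lm_))
    m_new <- colSums(g * A, na.rm = TRUE) /
      colSums(g * !is.na(A), na.rm = TRUE)
    u_new <- colSums((1 - g) * A, na.rm = TRUE) /
      colSums((1 - g) * !is.na(A), na.rm = TRUE)
    p_new <- mean(g)
    m_new <- pmin(pmax(m_new, 0.5), 0.999)
    u_new <- pmin(pmax(u_new, 0.001), 0.6)
    bad <- m_new <= u_new
    m_new[bad] <- pmin(u_new[bad] + 0.05, 0.999)
    if (max(abs(m_new - m), abs(u_new - u), abs(p_new - p)) < tol) {
      m <- m_new; u <- u_new; p <- p_new
      break
    }
    m <- m_new; u <- u_new; p <- p_new
  }
  match_params(m = setNames(m, FS_FIELDS), u = setNames(u, FS_FIELDS),
               jw_agreement_threshold = init$jw_agreement_threshold,
               winkler_prefix_scale = init$winkler_prefix_scale,
               winkler_max_prefix = init$winkler_max_prefix)
}
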