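---
title: "Linkage errors and their impact on time-to-event estimates: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linkage errors and their impact on time-to-event estimates: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its own methods: the linkage
model, the synthetic world it is exercised on, the outcome model, and the
design choices made where more than one defensible option existed.

## The problem

When clinic records are linked to a population registry on names, dates of
birth and residence rather than a unique identifier, two error types arise:
**false matches** (two different people linked) and **missed matches** (one
person's records not linked). In an analysis of the linked file — here, a
Cox regression of time from first HIV-positive diagnosis to care
registration on testing modality (community sero-survey vs walk-in clinic)
— false matches attach the wrong person's follow-up history to an exposure,
diluting the association toward the null, while missed matches shrink the
analytic sample and inflate standard errors. The package simulates the
whole chain so both effects can be measured against a known truth.

## Fellegi–Sunter scoring

Each encounter is compared to every registry person on nine fields:
personal names, household-member names and ten-cell-leader names (the
community leader of a ~10-household group, whose name is a stable, shared
identifier); and sex, birth year, birth month, birth day, village and
sub-village. A field with agreement probability $m$ among true matches and
$u$ among non-matches contributes $\log_2(m/u)$ when it agrees,
$\log_2\frac{1-m}{1-u}$ when it disagrees, and nothing when either side is
missing. The match score is the sum over comparable fields; the registry
person with the highest score is the best candidate.

Name fields are compared **order-relaxed**: people in this setting report
names in varying order, and the registry stores at most two names while
encounters may record three. The comparison takes the maximum Jaro–Winkler
similarity over all cross pairs of listed names and counts agreement when
it reaches `jw_agreement_threshold` (default 0.85, a conventional operating
point for name data; configurable). The Jaro–Winkler comparator itself is
the standard one: matching window $\lfloor\max(|a|,|b|)/2\rfloor-1$,
transpositions counted half each, Winkler prefix boost with scale 0.1
capped at 4 characters, applied unconditionally. The remaining fields are
compared by exact equality, with birth month/day compared only when present
on both sides.

**Parameter defaults.** $m$ defaults to 0.9 for name and date fields and
0.95 for sex and geography; default $u$ values are registry-scale agreement
rates (e.g. 0.5 for sex). Neither is treated as known truth:
`estimate_u_probabilities()` estimates $u$ as the per-field agreement rate
among randomly paired records, and `estimate_mu_em()` offers a standard
two-class EM refinement over sampled agreement patterns, clamped so
$m > u$ always holds. Scores are in log base 2 only for scale; ranking is
base-invariant.

**Thresholds.** Because absolute scores depend on the field set, analytic
datasets are built at *percentiles* of the true-match score distribution:
minimum, 25th, 50th and 75th (labelled minimum/low/medium/high). The
percentile is nearest-rank — the $\lceil p/100\cdot n\rceil$-th order
statistic — so percentile 0 is exactly the minimum observed true-match
score, with no interpolation ambiguity. Threshold comparison is inclusive
(score $\ge$ cutoff), which makes the minimum threshold retain every best
candidate: every encounter's best score is at least its own true-pair
score, hence at least the minimum over true pairs.

**Tie-breaking.** Equal best scores are resolved by fewest disagreeing
fields, then lowest `person_id`, and the tie is flagged. The field's
interactive linkage systems resolve such ties by human inspection;
a deterministic rule is used here so runs are reproducible.

**Blocking.** None by default: at the package's registry scale the full
cross product is affordable and avoids blocking-induced misses. Optional
blocking on sex + village is available for larger registries.

## The synthetic world

The generator emulates the statistical structure the analysis depends on,
not any real population:

- **Names** come from finite pools (default 40 given, 40 family names)
  built from fixed syllable sets, sampled with Zipf weights. Finite skewed
  pools force distinct people to collide on full names — the raw material
  of false matches — and syllable-built names produce near-misses in the
  Jaro–Winkler 0.8–1.0 range that the agreement threshold must
  discriminate. No attempt is made to model any real population's name
  distribution.
- **Structure:** households nested in sub-villages and villages, grouped
  under ten-cell leaders (default 10 households per leader); household
  members share location, coordinates and leader names; one or two
  non-overlapping residency episodes per person. Distance to the care
  clinic is planar Euclidean distance from household coordinates
  (kilometres), banded <1 / 1–1.9 / 2–4.9 / 5–11 km; at ward scale the
  planar approximation is adequate.
- **Corruption:** encounter identifiers are corrupted by per-name typos
  (one substitution, transposition or deletion, position uniform — the
  simplest mechanism that lands similarities in the near-miss range),
  name-order swaps, integer birth-year slips, month/day resampling, sex
  flips and sub-village misreports; field presence follows per-source
  completeness profiles (sero-survey vs clinic) mirroring the completeness
  observed in the motivating study's databases, e.g. first/second names
  ~100% everywhere, a third name 13.3% in sero-surveys vs 88.7% in
  clinics, household-member names 71.5% vs 11.3%. Paired
  leader/household-member name fields are generated nested (second present
  only with the first) while preserving the configured marginals.
- **Error-rate calibration.** The motivating study reports identifier
  *completeness* but not identifier *error rates*, so typo, geography and
  birth-date error rates are free parameters. The defaults (typo 0.25,
  sub-village error 0.30, birth-year/month/day error 0.45, registry 3,000,
  pools 40) were fixed once so that a default world reproduces the study's
  published error regime — roughly 60% sensitivity and a ~39% false-match
  rate at the minimum threshold, with PPV rising toward ~0.9+ at the high
  threshold — and were not tuned thereafter.
- **Outcome:** each cohort member's time to care registration is
  exponential with hazard
  $\lambda_0\exp(\beta_{\text{mod}}\,[\text{clinic}] + x^\top\gamma)$;
  the default $\beta_{\text{mod}} = \ln 5$, baseline
  $\lambda_0 = 0.0019$/day (about 16% registering within 90 days at
  reference levels), small covariate effects, a competing death process at
  $3\times10^{-4}$/day, and administrative censoring 90 days after
  diagnosis. The exponential baseline is the simplest generator compatible
  with the (semi-parametric) Cox analysis model. The default cohort is 405
  diagnoses split 263:142 between sero-survey and clinic (88.7% of clinic
  diagnoses at the HIV testing clinic, the rest antenatal), the analytic
  sample of the motivating study; modality-conditional covariate mixtures
  reproduce that study's descriptive table via importance-weighted
  sampling of registry persons, so cohort covariates remain consistent
  with registry attributes.
- **Eligibility:** ineligible encounters — under-15s, repeat testers,
  non-residents — are appended at configurable rates (defaults 4%/5%/4% of
  the cohort) purely so `apply_eligibility()` has something to do; they are
  excluded before linkage, as in the motivating analysis.
- **Dates** are integers (days) from an arbitrary study-start epoch; no
  calendar arithmetic is performed.

What the generator does **not** emulate: real name frequencies and
spelling variants, migration and registry round timing, correlated
field-level error (e.g. a fieldworker mis-recording several fields at
once), duplicate registry entries, and any human adjudication of candidate
matches. Passing tests therefore demonstrate the *mechanisms* of
linkage-error bias, not the magnitude to expect in any particular real
dataset.

## Linked-file analysis and the attenuation mechanism

An analyst holding only the linked file would take exposure and diagnosis
date from the encounter and everything else from the linked registry
person. The package does exactly that: covariates come from the linked
person's registry record, and the outcome is the linked person's care
history relative to the encounter's diagnosis date. Every registry person
carries a latent background registration/death history (exponential, low
rate — default $5\times10^{-4}$/day registration), drawn once per world,
so a falsely linked encounter deterministically inherits the wrong
person's, usually event-free, follow-up regardless of which threshold is
in force. This is the concrete mechanism by which false matches attenuate
the modality coefficient. Missed matches simply drop out, shrinking the
sample.

The Cox model uses Efron tie handling (day-granular times tie often;
Efron is the least-biased standard choice), a 1.96 normal multiplier for
95% intervals, and Wald statistics; internal identities
($\mathrm{HR}=e^\beta$, CI $=e^{\beta\pm1.96\,\mathrm{se}}$,
$\chi^2=(\beta/\mathrm{se})^2$) are asserted to $10^{-10}$ in the tests.
Same-day registration is set to 0.5 days to keep times positive.
Covariates reduced to a single observed level in a small thresholded
sample are dropped from that fit rather than failing it; a fit is declared
unfittable only when the modality term itself cannot be estimated, and the
experiment then continues with that row marked missing.

**Adjuster set.** The motivating study's methods list five adjusters (age,
sex, rurality, paved road, distance) while its results table footnote
lists four; the package follows the fuller five-adjuster specification by
default and exposes the set as an argument, so either can be requested.

**Precision regression.** The published correlation between missed matches
and precision loss is reported without naming the regressor scale; the
package regresses the modality-coefficient SE on the missed-match count
(the quantity the surrounding text emphasises) across the four thresholds
by ordinary least squares, with the p-value from the F test on 1 and 2
degrees of freedom. The per-threshold sensitivity, PPV and missed counts
are all in the report table, so a reader can regress on an alternative
scale if preferred.

## Numerical and degenerate-input conventions

- Score ties are detected at $10^{-9}$ absolute tolerance.
- Jaro–Winkler of an empty string is 0; only identical nonempty strings
  score 1. `NA` inputs propagate.
- A field missing on either side contributes no weight; an encounter with
  every field missing scores 0 against anyone.
- `m <= u` is rejected at configuration time (agreement must be evidence
  *for* a match); EM estimates are clamped to respect it.
- PPV of an empty linked dataset is `NaN` with a warning; a zero-variance
  standardised difference is `NaN`.
- All generation is seed-deterministic; replicate seeds are derived from
  the master seed by a counter scheme (`seed %% 1e6 * 1000 + r`), keeping
  every derived seed well under $2^{31}$.

## Problem sizes

The package's default study conditions — a 3,000-person registry with a
405-encounter cohort — keep a full generate–link–analyse experiment at
about two seconds, so the replicate studies (200 worlds) used by the test
suite and the acceptance script run in minutes on one CPU. The registry
size is a config field; the error-rate calibration above was done at the
default size, and users who scale the registry up should expect somewhat
higher false-match rates at equal corruption (more confusable candidates)
and may wish to re-estimate $u$.

## Known limitations

- One encounter links to at most one person (the best candidate); the
  package does not model one-to-many review lists beyond tie flags.
- The latent background-history device makes false-match outcomes
  deterministic per world but ignores that a falsely linked person might
  themselves be a cohort member whose true diagnosis precedes the
  encounter; their background history is used instead.
- Standardised-difference balance uses gold attributes for missed matches
  (they are unlinked, so only the synthetic truth can characterise them) —
  exactly what a real analyst could *not* do; the table exists to show
  selection, not to be reproducible on real data.
- The contingency utility applies Fisher's exact test only to 2×2 tables
  (switch rule: any expected cell below 5); larger sparse tables get the
  Pearson chi-square without continuity correction.
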