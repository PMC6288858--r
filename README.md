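# linkerr

**linkerr** is an R package for studying how probabilistic record-linkage
errors distort epidemiological analyses of linked data. It is aimed at
researchers who link clinic or survey records to a health and demographic
surveillance system (HDSS) registry without unique identifiers, and who need
to know what false matches (records of two different people erroneously
linked) and missed matches (records of the same person not linked) do to
downstream effect estimates.

The motivating analysis is a time-to-event question from an East African
HIV cohort: do people first diagnosed HIV-positive in a community
sero-survey register for HIV care at a different rate than people first
diagnosed at a walk-in clinic? Because the real registry and clinic records
are confidential, the package generates a fully synthetic world with known
gold-standard links, so every linkage error is observable and every bias
measurable.

## What the package does

1. **Synthetic world** (`generate_population()`, `simulate_cohort()`,
   `make_world()`): an HDSS person registry (names from finite Zipf-weighted
   pools, sex, date of birth, village/sub-village, household and ten-cell-
   leader structure, residency episodes, household coordinates) and
   encounter records whose identifiers are corrupted with configurable
   typos, name-order swaps, birth-date slips and source-specific field
   missingness. A two-level exposure (sero-survey vs clinic diagnosis),
   adjusting covariates, and an exponential proportional-hazards
   time-to-care-registration outcome with death and 90-day administrative
   censoring complete the cohort.

2. **Linkage engine** (`link_best_candidates()`, `score_pair()`,
   `jaro_winkler()`): Fellegi–Sunter scoring over nine matching fields. A
   field's evidence is `log2(m/u)` on agreement and `log2((1-m)/(1-u))` on
   disagreement, where `m` and `u` are the field's agreement probabilities
   among true matches and non-matches; missing fields contribute nothing.
   Name fields are compared order-relaxed: the maximum Jaro–Winkler
   similarity over all cross pairs of listed names, counted as agreement at
   a configurable threshold (default 0.85). The best-scoring registry
   person is selected per encounter; analytic datasets are built at
   percentile-based cutoffs (minimum / 25th / 50th / 75th percentile of the
   true-match score distribution).

3. **Error evaluation** (`classify_links()`, `link_metrics()`,
   `balance_table()`): true/false/missed classification against the gold
   standard; sensitivity, positive predictive value (PPV) and false-match
   rate per threshold; covariate balance between true, false and missed
   matches via standardised differences with the 0.2/0.5/0.8 anchors;
   chi-square / Fisher contingency tests.

4. **Outcome analysis** (`fit_cox()`, `threshold_experiment()`): Cox
   proportional-hazards fits (Efron ties) of the modality effect, adjusted
   for age group, sex, rurality, paved road and distance band, on the gold
   data and on each thresholded linked dataset — where a falsely linked
   encounter inherits the *wrong* person's registration history, the
   mechanism that attenuates the association. The report compares
   coefficients and standard errors across thresholds and regresses SE on
   the missed-match count.

## Worked example

```r
library(linkerr)

world  <- make_world(seed = 1)   # 3,000-person registry, 405-encounter cohort
report <- threshold_experiment(world)
print(report)
#> <threshold_report>
#>     label n_linked   ppv beta    se   hr
#> 1    gold      405    NA 1.63 0.252 5.12
#> 2 minimum      405 0.640 1.30 0.302 3.66
#> 3     low      373 0.686 1.42 0.314 4.13
#> 4  medium      227 0.890 1.72 0.376 5.56
#> 5    high      106 0.972 2.20 0.715 9.05
#> R^2(SE ~ missed) = 0.960 (p = 0.0203)
```

Reading the output: the generating truth is a hazard ratio of 5 for
clinic-based diagnosis. The gold-standard fit recovers it (HR 5.12). At the
minimum threshold every encounter links, but 36% of links are false; those
records carry the wrong person's (mostly event-free) care history, and the
estimate attenuates to HR 3.66. Raising the cutoff removes false matches
(PPV rises to 0.97) but discards true ones — the sample shrinks from 405 to
106 and the standard error nearly triples, with SE almost perfectly linear
in the missed-match count (R² = 0.96). Neither end of the threshold scale
gives an unbiased, precise answer; that trade-off is the package's subject.

`run_experiment()` wraps the same pipeline with CSV outputs and a run
manifest; `replicate_experiment()` repeats it over independently seeded
worlds; `verify_worked_examples()` recomputes the published metric
identities the implementation is checked against.

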