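# erplatency

Automatic extraction of ERP component latencies — built around a **dynamic
template-matching** algorithm for the P3 — for EEG researchers who want
expert-quality latencies without extracting them by hand.

## The idea

Subject-level ERPs are noisy; the grand average across subjects is not.
`erplatency` uses the grand average as a *template* and transforms it with
two free parameters to match each subject's waveform:

- an amplitude scale *a* (the template is multiplied by *a*), and
- a time stretch *b* (the value at time *t* moves to *t·b*, stimulus onset
  fixed, off-grid values spline-interpolated).

The optimal parameters are found either by minimizing a weighted sum of
squared distances (**MINSQ**, over *a* and *b*) or maximizing a weighted
correlation (**MAXCOR**, over *b* alone, since correlations ignore
amplitude), with per-timepoint weights built from a weighting window and a
weighting function (the default weights the match by the maximum-normalized
grand-average amplitude over 250–700 ms). Extreme stretches (*b* ≤ 2/3 or
*b* ≥ 1.5) are penalized by a factor e^b (or e^(1/b) for *b* < 1). The
subject's latency is then

> latency = b\* × l_GA,

where l_GA is the grand-average component latency (50%-area with a relative
baseline). Every fit also returns a **fit statistic** — the weighted
correlation between the transformed template and the subject ERP — and fits
with r < 0.3 are flagged for rejection or manual review.

The classical extractors (local peak latency, 50% fractional-area latency,
and the two relative-baseline area variants "Liesefeld A/B"), a split-half
latency-shift recovery simulation, absolute-agreement ICC and two-part
split-half alpha, and a synthetic-ERP generator round out the package.

## Worked example

```r
library(erplatency)

# a synthetic study: 20 subjects x 60 trials, each trial = transformed
# template + AR(1) noise; the true latency factors are known
study <- simulate_erp_study(n_subjects = 20, n_trials = 60, seed = 42)

latencies <- extract_latencies(study$erps, method = "minsq")
head(latencies, 3)
#> # A tibble: 3 × 9
#>   id    condition method a_opt b_opt fit_r latency_ms valid reject_reason
#>   <chr> <chr>     <chr>  <dbl> <dbl> <dbl>      <dbl> <lgl> <chr>
#> 1 S001  <NA>      minsq  1.32  1.13  0.992       438. TRUE  none
#> 2 S002  <NA>      minsq  0.806 1.13  0.983       441. TRUE  none
#> 3 S003  <NA>      minsq  1.37  0.865 0.994       336. TRUE  none
```

Each row is one waveform: the fitted amplitude scale `a_opt`, stretch
`b_opt`, the fit statistic `fit_r`, the recovered latency in ms, and a
validity flag (`reject_reason` says why a row was screened out: `low_fit`,
`degenerate`, `outlier` or `missing`). Here subject S003's P3 peaks about
13% earlier than the grand average, at ≈336 ms.

How trustworthy are such estimates? The recovery simulation injects a known
latency shift λ per subject between random trial-half averages, re-extracts,
and scores agreement between truth and recovery:

```r
rec <- run_shift_recovery(study, n_iterations = 10, seed = 42)
glance(rec)
#> # A tibble: 1 × 6
#>     icc n_subjects n_kept n_iterations missing_pct method
#>   <dbl>      <int>  <int>        <dbl>       <dbl> <chr>
#> 1 0.957         20     20           10           0 minsq
autoplot(rec)   # truth vs recovery scatter with the identity line
```

An ICC (absolute agreement) of 0.96 means the per-subject shifts were
recovered almost perfectly on this clean battery.

A thin command-line wrapper over the same functions ships in
`inst/cli/erplatency.R` (subcommands `synth`, `extract`, `simulate`,
`evaluate`, `grand-average`; every run writes a JSON manifest).

## Learn more

The methods vignette (`vignettes/template-matching.Rmd`) documents the
model, the weighting and penalty choices, the optimizer, the synthetic-data
assumptions and the package's known limitations.
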