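---
title: "Dynamic template matching for P3 latency extraction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic template matching for P3 latency extraction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(erplatency)
```

## The problem

The latency of an ERP component such as the P3 is a basic dependent
variable in mental-chronometry research, yet extracting it from
subject-level averages is notoriously unreliable: peak picking is
corrupted by high-frequency noise and overlapping components, and
fractional-area measures are sensitive to the measurement window. Manual
extraction by an expert works but does not scale and is hard to make
objective.

`erplatency` implements a different idea: treat the grand average across
subjects as a *dynamic template*. The grand average has an excellent
signal-to-noise ratio and, by construction, the morphology every subject
contributed to. Two free parameters transform it to match one subject's
waveform:

* an amplitude scale $a$, which simply multiplies the template, and
* a time stretch $b$, which maps the value at time $t$ of the template to
  time $t \cdot b$, with stimulus onset ($t = 0$) as the fixed point.
  Off-grid values are obtained by cubic-spline interpolation.

If the grand-average component latency is $l_{GA}$, the subject's latency
is recovered as $\hat{l}_j = b_j^{*} \, l_{GA}$, where $b_j^{*}$ is the
optimal stretch for subject $j$. $l_{GA}$ itself is measured once, on the
high-SNR grand average, with the 50%-area rule under a relative baseline
(see below), using the weighting window as measurement window.

## Objectives, weights, penalty

Two similarity measures are provided. **MINSQ** minimizes the weighted sum
of squared distances

$$\underset{a,b}{\arg\min} \sum_i \omega_i \left( t_i^{a,b} - s_i \right)^2,$$

where $t^{a,b}$ is the transformed template and $s$ the subject ERP.
**MAXCOR** maximizes the weighted Pearson correlation built from the
weighted covariance
$\mathrm{cov}(t^{a,b}, s; \omega) = \sum_i \omega_i (t_i^{a,b} - m_{t})(s_i - m_{s}) / \sum_i \omega_i$.
Correlations are invariant to amplitude scaling, so MAXCOR fixes $a = 1$
and optimizes $b$ alone.

The weight vector $\omega$ is built by `make_weights()` from a weighting
window (presets 200–700, 250–700, 250–900, 300–600 ms; 250–700 ms is the
default) and a weighting function: uniform (`none`), rectangular, Hamming
or Tukey ($\alpha = 0.25$) tapers spanning the window, or `normalized` —
the maximum-normalized grand-average amplitude inside the window, which
concentrates importance at the component peak. `normalized` is the default
because it is the variant that tracks expert extraction and recovers
simulated shifts best in our own simulations. Negative template lobes are
floored at zero by default (`normalized_abs = TRUE` uses magnitudes
instead); the windowed variant is the default because the taper-free
weights outside the component region otherwise let unrelated late activity
dominate. Weights live on the static template grid and are never warped.

Stretches far from 1 occasionally win on noise alone. The penalty
multiplies a minimized objective (divides a maximized one) by $e^b$ for
$b \ge 1.5$ and $e^{1/b}$ for $b \le 2/3$; the open band $(2/3, 1.5)$ is
penalty-free so plausible stretches are not biased toward 1. Bounds are
$a \in [0.2, 20]$ and $b \in [0.3, 2]$: the lower bound on $a$ keeps the
optimizer away from the flat-line solution, and the $b$ bounds keep enough
of the warped epoch inside the recorded support.

## Optimization and the fit statistic

The objective surface is cheap but multimodal, so `fit_template()` uses a
deterministic seeded multistart: a Latin-hypercube design over
$(\log a, b)$ (16 starts by default, always including $a = b = 1$), each
refined by bounded Nelder–Mead through a logistic reparameterisation. For
MAXCOR's one-dimensional problem the $b$ range is partitioned into
subintervals — with breakpoints at the penalty discontinuities $b = 2/3$
and $b = 1.5$ so each piece is continuous — and each is searched by
golden-section. Ties within $10^{-9}$ go to the candidate with $b$ closest
to 1, matching the penalty's conservatism. Everything is reproducible from
the configuration seed.

Whatever the objective, the *fit statistic* reported is the weighted
correlation between the optimally transformed template and the subject
ERP. Fits with $r < 0.3$ are flagged invalid (`screen_fit()`); in our
synthetic experiments waveforms without an identifiable component
essentially never reach this threshold, so the statistic doubles as an
automatic review flag.

Samples whose preimage $t/b$ falls outside the template's support receive
no value (the package never extrapolates) and are dropped from the sums;
MINSQ renormalizes the remaining weights to the total weight mass so that
objective values are comparable across $b$ and shrinking support is not
rewarded. Renormalization alone is not enough: with a free amplitude
scale, a stretch that leaves only a sliver of the weighting window inside
the support can fit that sliver perfectly and win on a near-zero
objective. A transform is therefore feasible only while at least half of
the weight mass retains support (`min_weight_fraction = 0.5` in
`match_config()`) — the same "more than 50% missing" consideration that
motivates the stretch bounds. Because the forward transform is used,
compression ($b < 1$) loses support at the epoch edges while $b \ge 1$
keeps the whole epoch.

A note on numerics: spline interpolation uses FMM endpoint conditions
(the `stats::splinefun` default). Natural boundary conditions force zero
curvature at the epoch edges and leave $\sim 10^{-5}$ µV artifacts there,
which is above the $10^{-6}$ reproducibility we hold the transform to
under composition and round-trip tests; FMM is knot-exact and composes to
$\sim 10^{-8}$.

## Classical extractors

For comparison the package re-implements the standard extractors on the
same interface: `peak_latency()` (largest in-window deflection exceeding
the mean of its three neighbours on both sides), `area_latency()`
(50%-area point of the negative-clipped signal, linearly interpolated),
and the two relative-baseline variants `liesefeld_a_latency()` (baseline
at 50% of the in-window maximum) and `liesefeld_b_latency()` (baseline at
30% of the peak, window constrained to the supra-baseline lobe containing
the peak). All assume a positive component and accept
`polarity = "negative"`. Ties in the peak search go to the earliest
sample; Liesefeld B's crossings are clamped to the window when a side
never crosses, and when several lobes exceed the baseline the one holding
the global in-window maximum defines the component.

## Synthetic data: what it emulates, what it does not

`simulate_erp_study()` generates the validation battery: a population
template of Gaussian components (default: N2-like, −2.5 µV at 250 ms,
SD 30 ms; P3-like, +9.4 µV at 370 ms, SD 80 ms, on a −200…998 ms grid at
2 ms), per-subject true factors $b_{true} \sim U(0.8, 1.2)$ and
$a_{true} \sim U(0.7, 1.4)$, and 80 trials per subject equal to the
transformed template plus stationary AR(1) noise ($\varphi = 0.9$,
marginal SD 3 µV). AR(1) rather than white noise is used so the residual
has the low-frequency structure of filtered EEG — white noise would make
template matching unrealistically easy. Trial-level latency jitter exists
as an option but is off by default so that the subject-level ground truth
stays exactly interpretable.

This emulates the statistical structure the matcher assumes — a dominant
positive component whose latency scales multiplicatively, preceded by a
negative deflection — but not real EEG: there is no alpha rhythm, no
overlapping slow components, no artifacts, no inter-subject morphology
differences beyond $(a, b)$. Passing the recovery tests therefore shows
the estimator is consistent under its own model, not that it is robust to
everything empirical data can do.

## The shift-recovery simulation

`run_shift_recovery()` implements the parameter-recovery protocol used to
validate extractors: each subject receives a true shift
$\lambda_j \sim N(0.9, 0.05^2)$, fixed across iterations and methods. Per
iteration, trials are randomly split into disjoint halves (50/50, chosen
to equalize the SNR of the two averages); the experimental half-average is
stretched by $\lambda_j$ with the same spline transform the matcher uses;
latencies are extracted from both ERPs; and the recovered shift is
$\hat{\lambda}_{i,j} = l_{exp} / l_{control}$. Because stretching by
$\lambda$ multiplies latencies by $\lambda$, this ratio estimates
$\lambda_j$ directly; the reciprocal convention is available as
`invert_ratio = TRUE` for comparability with analyses that report
$l_{control} / l_{exp}$. Screening removes template fits with $r < 0.3$ or
$b \notin (0.5, 1.9)$, then a single pooled 3-SD outlier pass across
subjects and iterations; subjects with fewer than 50% valid iterations are
dropped; the rest are averaged per subject and scored against the truth
with the absolute-agreement intraclass correlation.

## Evaluation statistics

`icc_absolute_agreement()` is the two-way random-effects, single-rater
ICC(A,1), computed from the explicit subjects × raters ANOVA mean
squares: $(MS_R - MS_E) / (MS_R + MS_E + \tfrac{2}{n}(MS_C - MS_E))$ for
$k = 2$. Absolute agreement penalizes systematic offsets, which a Pearson
correlation would ignore. `two_part_alpha()` is Cronbach's alpha over two
parts — here latencies from odd-trial and even-trial half-averages
(`split_half_reliability()`), the standard ERP split because it balances
slow drifts; raw-score alpha is the default with a standardized option
(which reduces exactly to the Spearman–Brown step-up of the Pearson
correlation). Both use pairwise deletion of missing values.

## Worked example

```{r example, eval = FALSE}
study <- simulate_erp_study(n_subjects = 20, n_trials = 60, seed = 42)
latencies <- extract_latencies(study$erps, method = "minsq")
head(latencies)

rec <- run_shift_recovery(study, n_iterations = 10, seed = 42)
glance(rec)
autoplot(rec)
```

## Problem sizes and defaults

The bundled validation battery is 60 subjects × 80 trials with 20
simulation iterations — the regime where the recovery ICC of the MINSQ +
normalized-weights + penalty pipeline is expected to reach 0.91 or more.
Property-style checks in the test suite (direction equivalence, extractor
ranking, screening monotonicity) run on reduced batteries (24–30 subjects,
8–10 iterations, 3 master seeds), sizes chosen so the full suite exercises
every screening path while each property still has comfortable headroom
over sampling noise.

## Known limitations

* Single channel, single component: no topography, no difference waves,
  no single-trial estimation.
* The template is assumed to contain the component; with very small
  samples the grand average itself is noisy and $l_{GA}$ inherits that
  noise.
* The multiplicative-shift model warps the entire epoch, including the
  pre-stimulus baseline; constant-offset latency differences are only
  approximated by a stretch.
* The classical extractors implement the common parameterisations, not
  every option of the original utilities.
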