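#' Gaussian component specification
#'
#' Synthetic ERPs are sums of Gaussian bumps. The default preset emulates a
#' parietal P3 epoch: an N2-like trough (-2.5 uV at 250 ms, SD 30 ms)
#' followed by a dominant P3-like deflection (+9.4 uV at 370 ms, SD 80 ms).
#'
#' @param center Peak time in ms.
#' @param width Gaussian SD in ms (> 0).
#' @param amplitude Signed peak amplitude in uV.
#' @return A one-row tibble; `default_components()` returns the two-row
#'   N2 + P3 preset.
#' @export
erp_component <- function(center, width, amplitude) {
  stopifnot(width > 0)
  tibble(center = center, width = width, amplitude = amplitude)
}

#' @rdname erp_component
#' @export
default_components <- function() {
  dplyr::bind_rows(
    erp_component(250, 30, -2.5),
    erp_component(370, 80, 9.4)
  )
}

#' Build a noise-free population template
#'
#' Evaluates the sum of Gaussian components on a uniform time grid. With the
#' defaults this is the "population grand average" that synthetic subjects
#' are derived from.
#'
#' @param components A tibble of [erp_component()] rows.
#' @param times Time grid in ms (default -200..998 ms at 2 ms steps, i.e.
#'   500 Hz sampling with a 200 ms pre-stimulus baseline).
#' @return An [erp_signal()].
#' @export
make_population_template <- function(components = default_components(),
                                     times = seq(-200, 998, by = 2)) {
  if (nrow(components) == 0) abort("Need at least one component.")
  vals <- rowSums(vapply(seq_len(nrow(components)), function(i) {
    components$amplitude[i] *
      exp(-(times - components$center[i])^2 / (2 * components$width[i]^2))
  }, numeric(length(times))))
  erp_signal(times, vals)
}

trial_seed <- function(seed, i) {
  as.integer((as.numeric(seed) + 104729 * as.numeric(i)) %% 2147483629) + 1L
}

# stationary AR(1) noise, phi = ar_phi, marginal SD = noise_sd
ar1_noise <- function(n, noise_sd, ar_phi, seed) {
  if (noise_sd == 0) return(numeric(n))
  withr::with_seed(seed, {
    as.numeric(arima.sim(
      model = list(ar = ar_phi), n = n,
      sd = noise_sd * sqrt(1 - ar_phi^2)
    ))
  })
}

#' Generate a synthetic subject's trials and ERP
#'
#' Each trial is the template stretched by the subject's true latency factor
#' `b_true`, scaled by `a_true`, plus stationary AR(1) noise (lag-1
#' autocorrelation `ar_phi`, marginal SD `noise_sd`), seeded deterministically
#' per trial. The subject ERP is the trial average. AR(1) noise is used
#' instead of white noise so the residual has the low-frequency structure of
#' filtered EEG. Optional trial-level latency jitter multiplies each trial's
#' stretch by `exp(rnorm(1, 0, jitter_sd))` (off by default so the ground
#' truth stays interpretable).
#'
#' @param template An [erp_signal()].
#' @param b_true,a_true True stretch and amplitude factors.
#' @param noise_sd Trial noise SD in uV (default 3).
#' @param n_trials Number of trials (default 80).
#' @param seed Integer seed.
#' @param ar_phi AR(1) coefficient (default 0.9).
#' @param jitter_sd Trial-level log-normal latency jitter SD (default 0).
#' @return A list with `erp` (an [erp_signal()]), `trials` (matrix, trials in
#'   rows) and `valid` (logical vector for the grid).
#' @export
generate_subject_erp <- function(template, b_true = 1, a_true = 1,
                                 noise_sd = 3, n_trials = 80, seed = 1L,
                                 ar_phi = 0.9, jitter_sd = 0) {
  stopifnot(n_trials >= 2, noise_sd >= 0)
  template <- as_erp_signal(template)
  n <- nrow(template)
  clean <- scale_amplitude(stretch_signal(template, b_true), a_true)
  trials <- matrix(NA_real_, nrow = n_trials, ncol = n)
  for (i in seq_len(n_trials)) {
    base <- clean
    if (jitter_sd > 0) {
      jit <- withr::with_seed(trial_seed(seed, 2 * i), exp(rnorm(1, 0, jitter_sd)))
      base <- scale_amplitude(stretch_signal(template, b_true * jit), a_true)
    }
    noise <- ar1_noise(n, noise_sd, ar_phi, trial_seed(seed, 2 * i + 1))
    trials[i, ] <- base$amplitude + noise
  }
  valid <- colSums(is.na(trials)) == 0
  avg <- colMeans(trials)
  list(
    erp = erp_signal(template$time, avg, valid),
    trials = trials,
    valid = valid
  )
}

#' Simulate a battery of synthetic subjects
#'
#' Draws per-subject true latency and amplitude factors, generates each
#' subject's trials with [generate_subject_erp()], and returns both the
#' ground truth and the data in tidy form. The defaults (60 subjects, 80
#' trials, AR(1) noise SD 3 uV, latency factors uniform on 0.8-1.2,
#' amplitude factors uniform on 0.7-1.4) mimic a single-condition P3 study
#' of moderate size.
#'
#' @param n_subjects Number of subjects (default 60).
#' @param n_trials Trials per subject (default 80).
#' @param noise_sd Trial noise SD in uV (default 3).
#' @param b_range,a_range Ranges for the uniform draws of the true latency
#'   and amplitude factors.
#' @param seed Master seed (default 1).
#' @param template Population template (default
#'   [make_population_template()]).
#' @param ar_phi,jitter_sd Passed to [generate_subject_erp()].
#' @return A list of class `erp_study`: `template`, `truth` (tibble with
#'   `id`, `b_true`, `a_true`, `seed`), `trials` (named list of matrices) and
#'   `erps` (long tibble `id`, `time`, `amplitude`).
#' @export
simulate_erp_study <- function(n_subjects = 60, n_trials = 80, noise_sd = 3,
                               b_range = c(0.8, 1.2), a_range = c(0.7, 1.4),
                               seed = 1L, template = make_population_template(),
                               ar_phi = 0.9, jitter_sd = 0) {
  stopifnot(n_subjects >= 1)
  ids <- sprintf("S%03d", seq_len(n_subjects))
  pars <- withr::with_seed(seed, tibble(
    id = ids,
    b_true = runif(n_subjects, b_range[1], b_range[2]),
    a_true = runif(n_subjects, a_range[1], a_range[2]),
    seed = trial_seed(seed, seq_len(n_subjects) * 31)
  ))
  subjects <- purrr::pmap(pars, function(id, b_true, a_true, seed) {
    generate_subject_erp(template, b_true, a_true, noise_sd, n_trials,
                         seed, ar_phi, jitter_sd)
  })
  names(subjects) <- ids
  erps <- signals_to_long(purrr::map(subjects, "erp"))
  structure(
    list(
      template = template,
      truth = pars,
      trials = purrr::map(subjects, "trials"),
      erps = erps,
      n_trials = n_trials,
      noise_sd = noise_sd,
      ar_phi = ar_phi
    ),
    class = "erp_study"
  )
}

#' @export
print.erp_study <- function(x, ...) {
  cat(sprintf(
    "<erp_study> %d subjects x %d trials, noise SD %g uV (AR1 phi %g)\n",
    nrow(x$truth), x$n_trials, x$noise_sd, x$ar_phi
  ))
  invisible(x)
}
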