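#' Draw true latency-shift parameters
#'
#' Seeded i.i.d. draws from `N(mu_lambda, sigma_lambda^2)`, one per subject,
#' fixed across all simulation iterations and extraction methods.
#'
#' @param n_subjects Number of subjects.
#' @param mu_lambda Mean shift (default 0.9).
#' @param sigma_lambda SD of the shift (default 0.05).
#' @param seed Integer seed.
#' @return Numeric vector of length `n_subjects`.
#' @export
draw_true_shifts <- function(n_subjects, mu_lambda = 0.9,
                             sigma_lambda = 0.05, seed = 1L) {
  stopifnot(n_subjects >= 1, sigma_lambda >= 0, mu_lambda > 0)
  withr::with_seed(seed, rnorm(n_subjects, mu_lambda, sigma_lambda))
}

# one split-half iteration for one subject: returns the recovered shift and
# bookkeeping, never throws on extraction failure
run_split_iteration <- function(trials, times, lambda, extract_fn, seed,
                                invert_ratio = FALSE) {
  n <- nrow(trials)
  stopifnot(n >= 2)
  idx <- withr::with_seed(seed, sample.int(n))
  ctrl <- idx[seq_len(floor(n / 2))]
  expi <- idx[(floor(n / 2) + 1):n]
  ctrl_erp <- erp_signal(times, colMeans(trials[ctrl, , drop = FALSE]))
  exp_erp <- stretch_signal(
    erp_signal(times, colMeans(trials[expi, , drop = FALSE])), lambda
  )
  res_c <- extract_fn(ctrl_erp)
  res_e <- extract_fn(exp_erp)
  lam <- if (invert_ratio) {
    res_c$latency / res_e$latency
  } else {
    res_e$latency / res_c$latency
  }
  tibble(
    lambda_hat = ifelse(is.finite(lam), lam, NA_real_),
    valid = res_c$valid && res_e$valid && is.finite(lam),
    fit_control = res_c$fit_r, fit_exp = res_e$fit_r,
    b_control = res_c$b_opt, b_exp = res_e$b_opt,
    latency_control = res_c$latency, latency_exp = res_e$latency
  )
}

#' Latency-shift recovery simulation
#'
#' The parameter-recovery protocol: each subject gets a true multiplicative
#' latency shift `lambda ~ N(mu_lambda, sigma_lambda^2)`. On every iteration
#' the subject's trials are randomly split into disjoint control and
#' experimental halves; the experimental half-average is stretched by the
#' subject's true shift (same spline transform as the matcher); latencies
#' are extracted from both ERPs and the recovered shift is their ratio
#' `l_exp / l_control` (the generation-consistent direction; set
#' `invert_ratio = TRUE` for `l_control / l_exp`). Estimates are screened
#' (template-fit `r < fit_cutoff`, stretch outside `b_valid`, then a single
#' pooled 3-SD outlier pass), subjects with fewer than `min_valid_fraction`
#' valid iterations are dropped, the rest are averaged per subject, and the
#' absolute-agreement ICC between true and mean recovered shifts is
#' computed.
#'
#' @param study An `erp_study` from [simulate_erp_study()].
#' @param method,window,weight_fn,penalty,fit_cutoff,n_starts Extraction
#'   settings (see [extract_latencies()]); classical extractors skip the
#'   fit-based screens.
#' @param n_iterations Number of random splits per subject (default 20).
#' @param mu_lambda,sigma_lambda True-shift distribution (defaults 0.9,
#'   0.05).
#' @param b_valid Open interval of plausible stretches; template estimates
#'   with `b <= b_valid[1]` or `b >= b_valid[2]` are invalid (default
#'   `c(0.5, 1.9)`).
#' @param outlier_sd Pooled z-score threshold (default 3).
#' @param min_valid_fraction Minimum fraction of valid iterations a subject
#'   needs to be retained (default 0.5).
#' @param invert_ratio Use the inverted ratio `l_control / l_exp`.
#' @param seed Master seed for shift draws and trial splits.
#' @return An object of class `shift_recovery`: list with `icc`, `subjects`
#'   (per-subject truth, mean recovery, validity counts), `iterations` (every
#'   recovered shift), `missing_pct` and the configuration.
#' @examples
#' \donttest{
#' study <- simulate_erp_study(n_subjects = 8, n_trials = 20, seed = 3)
#' rec <- run_shift_recovery(study, n_iterations = 4, seed = 3)
#' glance(rec)
#' }
#' @export
run_shift_recovery <- function(study, method = "minsq",
                               window = c(250, 700),
                               weight_fn = "normalized", penalty = TRUE,
                               fit_cutoff = 0.3, n_starts = 16,
                               n_iterations = 20, mu_lambda = 0.9,
                               sigma_lambda = 0.05, b_valid = c(0.5, 1.9),
                               outlier_sd = 3, min_valid_fraction = 0.5,
                               invert_ratio = FALSE, seed = 1L) {
  stopifnot(inherits(study, "erp_study"), n_iterations >= 1)
  template <- grand_average(study$erps)
  times <- template$time
  ids <- study$truth$id
  lambdas <- draw_true_shifts(length(ids), mu_lambda, sigma_lambda, seed)

  is_template_method <- method %in% c("minsq", "maxcor")
  if (is_template_method) {
    config <- match_config(method = method, window = window,
                           weight_fn = weight_fn, penalty = penalty,
                           fit_cutoff = fit_cutoff, n_starts = n_starts,
                           seed = seed)
    w <- make_weights(template, window, weight_fn)$weight
    prep <- prepare_match(template, w)
    l_ga <- liesefeld_a_latency(template, window = window)
    extract_fn <- function(sig) {
      fit <- fit_template_prepared(sig$amplitude, sig$valid, prep, config, l_ga)
      list(
        latency = fit$latency_ms,
        valid = fit$valid && !is.na(fit$b_opt) &&
          fit$b_opt > b_valid[1] && fit$b_opt < b_valid[2],
        fit_r = fit$fit_r, b_opt = fit$b_opt
      )
    }
  } else {
    extractor <- switch(method,
      peak = peak_latency, area = area_latency,
      liesefeld_a = liesefeld_a_latency, liesefeld_b = liesefeld_b_latency,
      abort(sprintf("Unknown method `%s`.", method))
    )
    win <- if (is.null(window)) {
      if (method == "peak") c(250, 900) else c(250, 700)
    } else {
      window
    }
    extract_fn <- function(sig) {
      lat <- extractor(sig, window = win)
      list(latency = lat, valid = !is.na(lat), fit_r = NA_real_,
           b_opt = NA_real_)
    }
  }

  grid <- tidyr::expand_grid(subject = seq_along(ids),
                             iteration = seq_len(n_iterations))
  draws <- purrr::pmap_dfr(grid, function(subject, iteration) {
    res <- run_split_iteration(
      trials = study$trials[[subject]], times = times,
      lambda = lambdas[subject], extract_fn = extract_fn,
      seed = trial_seed(seed, subject * 1000 + iteration),
      invert_ratio = invert_ratio
    )
    dplyr::bind_cols(
      tibble(id = ids[subject], iteration = iteration,
             lambda_true = lambdas[subject]),
      res
    )
  })

  summarize_recovery(draws, outlier_sd = outlier_sd,
                     min_valid_fraction = min_valid_fraction,
                     n_iterations = n_iterations,
                     config = list(
                       method = method, window = window,
                       weight_fn = weight_fn, penalty = penalty,
                       fit_cutoff = fit_cutoff, b_valid = b_valid,
                       mu_lambda = mu_lambda, sigma_lambda = sigma_lambda,
                       invert_ratio = invert_ratio, seed = seed
                     ))
}

#' Summarize recovered shifts into per-subject means and an ICC
#'
#' Applies the pooled single-pass 3-SD outlier rule to the valid recovered
#' shifts, drops subjects with fewer than `min_valid_fraction` valid
#' iterations, averages the surviving estimates per subject, and computes
#' the absolute-agreement ICC against the true shifts.
#'
#' @param draws Iteration-level tibble with columns `id`, `iteration`,
#'   `lambda_true`, `lambda_hat`, `valid` (as produced inside
#'   [run_shift_recovery()]).
#' @param outlier_sd,min_valid_fraction,n_iterations Screening settings.
#' @param config Configuration list echoed into the result.
#' @return A `shift_recovery` object.
#' @export
summarize_recovery <- function(draws, outlier_sd = 3,
                               min_valid_fraction = 0.5,
                               n_iterations = max(draws$iteration),
                               config = list()) {
  stopifnot(all(c("id", "lambda_true", "lambda_hat", "valid") %in%
                  names(draws)))
  pool <- draws$lambda_hat[draws$valid]
  if (length(pool) >= 3 && sd(pool) > 0) {
    z <- abs(draws$lambda_hat - mean(pool)) / sd(pool)
    outlier <- draws$valid & !is.na(z) & z > outlier_sd
    draws$valid[outlier] <- FALSE
    draws$outlier <- outlier
  } else {
    draws$outlier <- FALSE
  }
  subjects <- draws |>
    dplyr::group_by(.data$id) |>
    dplyr::summarise(
      lambda_true = .data$lambda_true[1],
      lambda_hat = mean(.data$lambda_hat[.data$valid]),
      n_valid = sum(.data$valid),
      .groups = "drop"
    ) |>
    dplyr::mutate(kept = .data$n_valid >= min_valid_fraction * n_iterations &
                    is.finite(.data$lambda_hat))
  kept <- dplyr::filter(subjects, .data$kept)
  if (nrow(kept) < 2) {
    abort("Fewer than 2 subjects survived screening; cannot compute an ICC.")
  }
  icc <- icc_absolute_agreement(kept$lambda_true, kept$lambda_hat)
  structure(
    list(
      icc = icc,
      subjects = subjects,
      iterations = draws,
      missing_pct = 100 * mean(!draws$valid),
      n_iterations = n_iterations,
      config = config
    ),
    class = "shift_recovery"
  )
}

#' @export
print.shift_recovery <- function(x, ...) {
  cat(sprintf(
    "<shift_recovery %s> ICC(A,1) = %.3f, %d/%d subjects kept, %.1f%% invalid iterations\n",
    x$config$method %||% "?", x$icc, sum(x$subjects$kept),
    nrow(x$subjects), x$missing_pct
  ))
  invisible(x)
}
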