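#' Tidy a template fit
#'
#' @param x A `template_fit` from [fit_template()].
#' @param ... Unused.
#' @return One row per estimated parameter (`a` is fixed at 1 for MAXCOR and
#'   omitted).
#' @exportS3Method generics::tidy
tidy.template_fit <- function(x, ...) {
  pars <- tibble(
    parameter = c("a", "b"),
    estimate = c(x$a_opt, x$b_opt)
  )
  if (x$config$method == "maxcor") pars <- pars[pars$parameter == "b", ]
  pars
}

#' @rdname tidy.template_fit
#' @exportS3Method generics::glance
glance.template_fit <- function(x, ...) {
  tibble(
    method = x$config$method,
    a_opt = x$a_opt, b_opt = x$b_opt,
    objective = x$objective, fit_r = x$fit_r,
    l_ga = x$l_ga, latency_ms = x$latency_ms,
    valid = x$valid, reject_reason = x$reject_reason
  )
}

#' Tidy a shift-recovery result
#'
#' @param x A `shift_recovery` from [run_shift_recovery()].
#' @param ... Unused.
#' @return `tidy()`: the per-subject table (true shift, mean recovered
#'   shift, valid-iteration count, whether the subject was kept).
#'   `glance()`: a one-row summary with the ICC and missingness.
#' @exportS3Method generics::tidy
tidy.shift_recovery <- function(x, ...) {
  x$subjects
}

#' @rdname tidy.shift_recovery
#' @exportS3Method generics::glance
glance.shift_recovery <- function(x, ...) {
  tibble(
    icc = x$icc,
    n_subjects = nrow(x$subjects),
    n_kept = sum(x$subjects$kept),
    n_iterations = x$n_iterations,
    missing_pct = x$missing_pct,
    method = x$config$method %||% NA_character_
  )
}
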