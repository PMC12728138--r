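#' Construct a sampled ERP signal
#'
#' An `erp_signal` is a tibble with columns `time` (milliseconds, uniform
#' grid containing stimulus onset at exactly 0 ms), `amplitude` (microvolts)
#' and `valid` (logical; `FALSE` marks samples without interpolation support,
#' e.g. after a time-axis stretch pushed their preimage outside the recorded
#' epoch). Invalid samples carry `NA` amplitudes; no value is ever
#' extrapolated into them.
#'
#' @param time Numeric vector of sample times in ms. Must be strictly
#'   increasing with a constant step (tolerance 1e-9 ms) and contain 0.
#' @param amplitude Numeric vector of voltages in microvolts, same length as
#'   `time`. `NA` entries are marked invalid.
#' @param valid Optional logical vector; defaults to `!is.na(amplitude)`.
#'
#' @return A tibble of class `erp_signal`.
#' @examples
#' tt <- seq(-200, 998, by = 2)
#' sig <- erp_signal(tt, 9.4 * exp(-(tt - 370)^2 / (2 * 80^2)))
#' @export
erp_signal <- function(time, amplitude, valid = NULL) {
  time <- as.numeric(time)
  amplitude <- as.numeric(amplitude)
  if (length(time) != length(amplitude)) {
    abort("`time` and `amplitude` must have the same length.")
  }
  if (is.null(valid)) valid <- !is.na(amplitude)
  if (length(valid) != length(time)) {
    abort("`valid` must have the same length as `time`.")
  }
  valid <- valid & !is.na(amplitude)
  amplitude[!valid] <- NA_real_
  check_time_grid(time)
  x <- tibble(time = time, amplitude = amplitude, valid = valid)
  class(x) <- c("erp_signal", class(x))
  x
}

# validates uniform, strictly increasing grid containing t = 0
check_time_grid <- function(time) {
  if (length(time) < 2) abort("A signal needs at least two samples.")
  steps <- diff(time)
  if (any(steps <= 0)) abort("`time` must be strictly increasing.")
  if (max(steps) - min(steps) > .time_tol) {
    abort(sprintf(
      "`time` must be a uniform grid (step varies by %.3g ms).",
      max(steps) - min(steps)
    ))
  }
  if (!any(abs(time) <= .time_tol)) {
    abort("`time` must contain stimulus onset t = 0 ms.")
  }
  invisible(time)
}

#' @export
#' @rdname erp_signal
#' @param x Object to test or coerce.
is_erp_signal <- function(x) inherits(x, "erp_signal")

#' @export
#' @rdname erp_signal
#' @details `as_erp_signal()` accepts a data frame with `time` and
#'   `amplitude` columns (and optionally `valid`).
as_erp_signal <- function(x) {
  if (is_erp_signal(x)) return(x)
  if (!is.data.frame(x) || !all(c("time", "amplitude") %in% names(x))) {
    abort("`x` must be a data frame with `time` and `amplitude` columns.")
  }
  erp_signal(x$time, x$amplitude, x$valid)
}

#' @export
print.erp_signal <- function(x, ...) {
  step <- diff(x$time[1:2])
  cat(sprintf(
    "<erp_signal> %d samples, %g..%g ms (step %g ms), %d invalid\n",
    nrow(x), x$time[1], x$time[nrow(x)], step, sum(!x$valid)
  ))
  NextMethod()
}

sampling_step <- function(signal) diff(signal$time[1:2])

onset_index <- function(signal) which(abs(signal$time) <= .time_tol)[1]

# cubic spline through the valid samples (FMM endpoint conditions: exact at
# the knots and free of the spurious edge curvature a natural spline clamps in)
signal_spline <- function(signal) {
  ok <- signal$valid
  if (sum(ok) < 4) {
    abort("Spline interpolation needs at least 4 valid samples.")
  }
  list(
    fun = splinefun(signal$time[ok], signal$amplitude[ok], method = "fmm"),
    support = range(signal$time[ok])
  )
}

#' Stretch or compress a signal along the time axis
#'
#' Applies the time-axis transformation that defines the dynamic template:
#' the output at time `t` equals the cubic-spline interpolated value of the
#' input at `t / b`, so every feature at time `t` moves to `t * b`. The fixed
#' point of the transformation is stimulus onset (t = 0 ms); pre-stimulus
#' samples are warped like the rest of the epoch. The output stays on the
#' input's time grid. Samples whose preimage `t / b` falls outside the input's
#' valid support receive no value and are flagged invalid -- the function
#' never extrapolates. For `b >= 1` every preimage stays inside the epoch;
#' for `b < 1` support is lost at the late edge of the epoch.
#'
#' @param signal An [erp_signal()].
#' @param b Positive stretch factor. `b > 1` delays features (stretches),
#'   `b < 1` moves them earlier (compresses).
#' @return An [erp_signal()] on the same grid.
#' @examples
#' tt <- seq(-200, 998, by = 2)
#' tmpl <- erp_signal(tt, 9.4 * exp(-(tt - 370)^2 / (2 * 80^2)))
#' stretched <- stretch_signal(tmpl, 1.1)
#' # the 9.4 uV value at 370 ms now sits at 370 * 1.1 = 407 ms
#' stretched$amplitude[stretched$time == 407]
#' @export
stretch_signal <- function(signal, b) {
  signal <- as_erp_signal(signal)
  if (!is.numeric(b) || length(b) != 1 || !is.finite(b) || b <= 0) {
    abort("`b` must be a single positive number.")
  }
  sp <- signal_spline(signal)
  pre <- signal$time / b
  ok <- pre >= sp$support[1] - .time_tol & pre <= sp$support[2] + .time_tol
  vals <- rep(NA_real_, nrow(signal))
  vals[ok] <- sp$fun(pre[ok])
  erp_signal(signal$time, vals, ok)
}

#' Scale a signal along the amplitude axis
#'
#' Multiplies every voltage by `a`; times and validity are untouched.
#'
#' @param signal An [erp_signal()].
#' @param a Positive amplitude scale factor.
#' @return An [erp_signal()].
#' @export
scale_amplitude <- function(signal, a) {
  signal <- as_erp_signal(signal)
  if (!is.numeric(a) || length(a) != 1 || !is.finite(a) || a <= 0) {
    abort("`a` must be a single positive number.")
  }
  erp_signal(signal$time, signal$amplitude * a, signal$valid)
}

#' Grand-average a set of ERP signals
#'
#' Pointwise mean across signals sharing one time grid. A timepoint is valid
#' in the average only if it is valid in every input.
#'
#' @param x A list of [erp_signal()] objects, or a long data frame with
#'   columns `id`, `time`, `amplitude` (as returned by [read_erp_matrix()] or
#'   [simulate_erp_study()]).
#' @return An [erp_signal()].
#' @export
grand_average <- function(x) {
  signals <- as_signal_list(x)
  if (length(signals) == 0) abort("Need at least one signal to average.")
  ref <- signals[[1]]
  mats <- vapply(signals, function(s) {
    if (nrow(s) != nrow(ref) || max(abs(s$time - ref$time)) > .time_tol) {
      abort("All signals must share the same time grid.")
    }
    s$amplitude
  }, numeric(nrow(ref)))
  valid <- rowSums(!vapply(signals, function(s) s$valid, logical(nrow(ref)))) == 0
  avg <- rowMeans(mats)
  avg[!valid] <- NA_real_
  erp_signal(ref$time, avg, valid)
}

# coerce a list of signals or a long (id, time, amplitude) frame to a list
as_signal_list <- function(x) {
  if (is_erp_signal(x)) return(list(x))
  if (is.data.frame(x)) {
    if (!all(c("id", "time", "amplitude") %in% names(x))) {
      abort("Long-format ERP data needs `id`, `time` and `amplitude` columns.")
    }
    split_x <- split(x, factor(x$id, levels = unique(x$id)))
    return(lapply(split_x, function(d) erp_signal(d$time, d$amplitude)))
  }
  if (is.list(x)) return(lapply(x, as_erp_signal))
  abort("Cannot interpret `x` as ERP signals.")
}

# long tibble view of a named list of signals
signals_to_long <- function(signals) {
  ids <- names(signals) %||% as.character(seq_along(signals))
  purrr::map2_dfr(signals, ids, function(s, id) {
    tibble(id = id, time = s$time, amplitude = s$amplitude)
  })
}
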