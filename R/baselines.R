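#' Classical latency extractors
#'
#' Reference extractors operating directly on a subject-level waveform:
#' local peak latency, 50 percent fractional-area latency, and the two
#' relative-baseline area variants of Liesefeld. All assume a positive-going
#' component (the P3); set `polarity = "negative"` to negate the signal
#' first. Each returns a latency in ms, or `NA` when the rule finds no
#' component.
#'
#' \describe{
#'   \item{`peak_latency()`}{time of the largest in-window voltage that
#'     exceeds the mean of its three neighbours on both sides (which discards
#'     one-sample noise spikes); ties go to the earliest sample. Default
#'     window 250-900 ms.}
#'   \item{`area_latency()`}{negative values are clipped to 0, the clipped
#'     signal is summed across the window, and the latency is the linearly
#'     interpolated time at which the cumulative sum crosses `frac` (default
#'     50 percent) of the total. Default window 250-700 ms.}
#'   \item{`liesefeld_a_latency()`}{like `area_latency()` after subtracting a
#'     relative baseline of 50 percent of the in-window maximum and clipping
#'     at 0, so only the upper half of the component contributes.}
#'   \item{`liesefeld_b_latency()`}{uses 30 percent of the in-window peak as
#'     the baseline and additionally restricts the measurement window to the
#'     supra-baseline lobe containing the peak (the component's onset and
#'     offset crossings); the 50 percent-area latency is then computed on the
#'     baseline-subtracted signal inside that lobe.}
#' }
#'
#' @param signal An [erp_signal()].
#' @param window `c(lower, upper)` measurement window in ms.
#' @param frac Area fraction for `area_latency()` (default 0.5).
#' @param polarity `"positive"` (default) or `"negative"`.
#' @return Latency in ms, or `NA_real_`.
#' @examples
#' tt <- seq(-200, 998, by = 2)
#' sig <- erp_signal(tt, 8 * exp(-(tt - 400)^2 / (2 * 60^2)))
#' peak_latency(sig)
#' area_latency(sig)
#' @name baseline_extractors
NULL

prep_polarity <- function(signal, polarity) {
  polarity <- rlang::arg_match0(polarity, c("positive", "negative"))
  signal <- as_erp_signal(signal)
  if (polarity == "negative") {
    signal <- erp_signal(signal$time, -signal$amplitude, signal$valid)
  }
  signal
}

#' @rdname baseline_extractors
#' @export
peak_latency <- function(signal, window = c(250, 900),
                         polarity = c("positive", "negative")) {
  signal <- prep_polarity(signal, polarity)
  check_window(window, signal$time)
  t <- signal$time
  v <- signal$amplitude
  n <- length(v)
  idx <- which(t >= window[1] - .time_tol & t <= window[2] + .time_tol)
  if (length(idx) < 7) abort("Peak window must contain at least 7 samples.")
  # candidates need 3 in-epoch neighbours on each side
  idx <- idx[idx >= 4 & idx <= n - 3]
  qualifies <- vapply(idx, function(i) {
    vi <- v[i]
    left <- v[(i - 3):(i - 1)]
    right <- v[(i + 1):(i + 3)]
    !is.na(vi) && !anyNA(left) && !anyNA(right) &&
      vi > mean(left) && vi > mean(right)
  }, logical(1))
  idx <- idx[qualifies]
  if (length(idx) == 0) return(NA_real_)
  t[idx[which.max(v[idx])]]
}

# 50%-area crossing of a nonnegative sample sequence; linear interpolation
# between the cumulative sums bracketing frac * total
area_crossing <- function(times, vals, frac) {
  vals[is.na(vals)] <- 0
  total <- sum(vals)
  if (total <= 0) return(NA_real_)
  cs <- cumsum(vals)
  target <- frac * total
  k <- which(cs >= target)[1]
  dt <- if (length(times) > 1) diff(times[1:2]) else 0
  prev_cs <- if (k == 1) 0 else cs[k - 1]
  prev_t <- if (k == 1) times[1] - dt else times[k - 1]
  prev_t + (target - prev_cs) / (cs[k] - prev_cs) * (times[k] - prev_t)
}

window_samples <- function(signal, window) {
  check_window(window, signal$time)
  which(signal$time >= window[1] - .time_tol &
          signal$time <= window[2] + .time_tol)
}

#' @rdname baseline_extractors
#' @export
area_latency <- function(signal, window = c(250, 700), frac = 0.5,
                         polarity = c("positive", "negative")) {
  signal <- prep_polarity(signal, polarity)
  idx <- window_samples(signal, window)
  area_crossing(signal$time[idx], pmax(signal$amplitude[idx], 0), frac)
}

#' @rdname baseline_extractors
#' @export
liesefeld_a_latency <- function(signal, window = c(250, 700), frac = 0.5,
                                polarity = c("positive", "negative")) {
  signal <- prep_polarity(signal, polarity)
  idx <- window_samples(signal, window)
  v <- signal$amplitude[idx]
  m <- suppressWarnings(max(v, na.rm = TRUE))
  if (!is.finite(m) || m <= 0) return(NA_real_)
  area_crossing(signal$time[idx], pmax(v - 0.5 * m, 0), frac)
}

#' @rdname baseline_extractors
#' @export
liesefeld_b_latency <- function(signal, window = c(250, 700), frac = 0.5,
                                polarity = c("positive", "negative")) {
  signal <- prep_polarity(signal, polarity)
  idx <- window_samples(signal, window)
  t <- signal$time[idx]
  v <- signal$amplitude[idx]
  v[is.na(v)] <- 0
  m <- max(v)
  if (m <= 0) return(NA_real_)
  p <- which.max(v) # earliest global in-window maximum
  beta <- 0.3 * m
  # lobe containing the peak: walk out to the first sub-baseline sample
  left <- p
  while (left > 1 && v[left - 1] >= beta) left <- left - 1
  right <- p
  while (right < length(v) && v[right + 1] >= beta) right <- right + 1
  area_crossing(t[left:right], pmax(v[left:right] - beta, 0), frac)
}
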