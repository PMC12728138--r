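#' Weighting windows for the P3
#'
#' The matching objectives weight each timepoint by a vector built from a
#' weighting window (when the component occurs) and a weighting function
#' (how importance falls off inside/outside it). Four window presets are
#' supported, in ms: 200-700, 250-700 (default; also the classical area
#' measurement window), 250-900 (the classical peak window) and 300-600.
#'
#' @return A named list of `c(lower, upper)` windows in ms.
#' @export
preset_windows <- function() {
  list(
    "200-700" = c(200, 700),
    "250-700" = c(250, 700),
    "250-900" = c(250, 900),
    "300-600" = c(300, 600)
  )
}

check_window <- function(window, times) {
  if (length(window) != 2 || !is.numeric(window) || window[1] >= window[2]) {
    abort("`window` must be c(lower, upper) with lower < upper (ms).")
  }
  if (window[1] < min(times) - .time_tol || window[2] > max(times) + .time_tol) {
    abort(sprintf(
      "Window [%g, %g] ms lies outside the epoch [%g, %g] ms.",
      window[1], window[2], min(times), max(times)
    ))
  }
  invisible(window)
}

# standard Tukey (tapered-cosine) window, alpha = taper fraction
tukey_taper <- function(n, alpha = 0.25) {
  if (n == 1) return(1)
  x <- seq(0, 1, length.out = n)
  w <- rep(1, n)
  lo <- x < alpha / 2
  hi <- x > 1 - alpha / 2
  w[lo] <- 0.5 * (1 + cos(pi * (2 * x[lo] / alpha - 1)))
  w[hi] <- 0.5 * (1 + cos(pi * (2 * x[hi] / alpha - 2 / alpha + 1)))
  w
}

#' Build a per-timepoint weight vector
#'
#' Combines a weighting window with a weighting function to produce the
#' nonnegative weights used by the template-matching objectives. Weights are
#' attached to the static template grid and are never warped.
#'
#' Functions:
#' \describe{
#'   \item{`none`}{weight 1 at every timepoint in the epoch, ignoring the
#'     window.}
#'   \item{`rectangular`}{1 inside the window, 0 outside (a Tukey window with
#'     alpha = 0, i.e. Dirichlet).}
#'   \item{`hamming`}{Hamming taper spanning exactly the window's samples,
#'     0 outside.}
#'   \item{`tukey25`}{Tukey taper with alpha = 0.25 spanning the window,
#'     0 outside; flat at 1 over the central 75 percent.}
#'   \item{`normalized`}{maximum-normalized template amplitude inside the
#'     window (negative amplitudes floored at 0, or absolute values with
#'     `normalized_abs = TRUE`), 0 outside. Puts maximal importance on the
#'     component peak of the grand average.}
#' }
#' All outputs are max-normalized to 1.
#'
#' @param template An [erp_signal()]; only used by `fn = "normalized"`, but
#'   always supplies the time grid.
#' @param window `c(lower, upper)` in ms, inside the epoch.
#' @param fn Weighting function name (see Details).
#' @param normalized_abs If `TRUE`, `normalized` uses `abs(amplitude)` rather
#'   than flooring negative lobes at 0.
#' @return A tibble of class `erp_weights` with columns `time` and `weight`.
#' @export
make_weights <- function(template, window = c(250, 700),
                         fn = c("normalized", "none", "rectangular",
                                "hamming", "tukey25"),
                         normalized_abs = FALSE) {
  template <- as_erp_signal(template)
  fn <- rlang::arg_match(fn)
  times <- template$time
  check_window(window, times)
  inside <- times >= window[1] - .time_tol & times <= window[2] + .time_tol
  n_in <- sum(inside)
  if (n_in < 2) abort("Weighting window covers fewer than 2 samples.")
  w <- numeric(length(times))
  if (fn == "none") {
    w[] <- 1
  } else if (fn == "rectangular") {
    w[inside] <- 1
  } else if (fn == "hamming") {
    w[inside] <- signal::hamming(n_in)
  } else if (fn == "tukey25") {
    w[inside] <- tukey_taper(n_in, alpha = 0.25)
  } else { # normalized
    amp <- template$amplitude[inside]
    amp[is.na(amp)] <- 0
    base <- if (normalized_abs) abs(amp) else pmax(amp, 0)
    if (max(base) <= 0) {
      abort("Template has no positive amplitude inside the window; cannot build normalized weights.")
    }
    w[inside] <- base
  }
  w <- w / max(w)
  out <- tibble(time = times, weight = w)
  class(out) <- c("erp_weights", class(out))
  out
}
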