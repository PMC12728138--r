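#' Absolute-agreement intraclass correlation, ICC(A,1)
#'
#' Two-way random-effects, single-rater ICC for absolute agreement between
#' two paired measurement series (McGraw & Wong):
#' `(MSR - MSE) / (MSR + (k - 1) MSE + (k / n) (MSC - MSE))` with `k = 2`,
#' computed from the explicit two-way ANOVA mean squares (subjects x
#' raters). Unlike a Pearson correlation, a constant offset between the two
#' series lowers the ICC, which is what "absolute agreement" means.
#' Incomplete pairs are dropped (pairwise deletion).
#'
#' @param x,y Equal-length numeric vectors, paired by subject.
#' @return ICC in \[-1, 1\].
#' @examples
#' icc_absolute_agreement(1:10, 1:10 + rnorm(10, sd = 0.1))
#' @export
icc_absolute_agreement <- function(x, y) {
  if (length(x) != length(y)) abort("`x` and `y` must be paired (equal length).")
  ok <- complete.cases(x, y)
  x <- x[ok]
  y <- y[ok]
  n <- length(x)
  if (n < 2) abort("Need at least 2 complete pairs.")
  k <- 2
  m <- cbind(x, y)
  gm <- mean(m)
  if (sum((m - gm)^2) <= 0) {
    abort("Zero total variance: ICC undefined.",
          class = "erplatency_degenerate")
  }
  row_m <- rowMeans(m)
  col_m <- colMeans(m)
  ssr <- k * sum((row_m - gm)^2)
  ssc <- n * sum((col_m - gm)^2)
  sst <- sum((m - gm)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}

#' Two-part coefficient alpha (split-half reliability)
#'
#' Cronbach's alpha over two parts, here latencies extracted from odd-trial
#' and even-trial half-averages:
#' `alpha = 2 * (1 - (var(p1) + var(p2)) / var(p1 + p2))`.
#' With `standardize = TRUE` the parts are z-scored first, in which case
#' alpha equals the Spearman-Brown formula `2 r / (1 + r)` applied to their
#' Pearson correlation. Incomplete pairs are dropped.
#'
#' @param part1,part2 Equal-length numeric vectors of half latencies.
#' @param standardize Use standardized alpha (default `FALSE`, raw-score).
#' @return Alpha (at most 1; can be negative).
#' @export
two_part_alpha <- function(part1, part2, standardize = FALSE) {
  if (length(part1) != length(part2)) {
    abort("`part1` and `part2` must be paired (equal length).")
  }
  ok <- complete.cases(part1, part2)
  part1 <- part1[ok]
  part2 <- part2[ok]
  if (length(part1) < 3) abort("Need at least 3 complete pairs.")
  if (standardize) {
    part1 <- as.numeric(scale(part1))
    part2 <- as.numeric(scale(part2))
  }
  vs <- var(part1 + part2)
  if (!is.finite(vs) || vs <= 0) {
    abort("Zero variance of the sum: alpha undefined.",
          class = "erplatency_degenerate")
  }
  2 * (1 - (var(part1) + var(part2)) / vs)
}

#' Split-half reliability of an extraction method on a synthetic study
#'
#' Splits every subject's trials into odd and even halves, averages each
#' half, extracts latencies from both half-averages with the requested
#' method, and returns the two-part coefficient alpha across subjects.
#'
#' @param study An `erp_study` from [simulate_erp_study()].
#' @param method,window,weight_fn,penalty Passed to [extract_latencies()].
#' @param standardize Passed to [two_part_alpha()].
#' @return A list with `alpha` and the per-subject `halves` tibble.
#' @export
split_half_reliability <- function(study, method = "minsq",
                                   window = NULL, weight_fn = "normalized",
                                   penalty = TRUE, standardize = FALSE) {
  stopifnot(inherits(study, "erp_study"))
  times <- study$template$time
  halves <- purrr::imap(study$trials, function(tr, id) {
    odd <- colMeans(tr[seq(1, nrow(tr), by = 2), , drop = FALSE])
    even <- colMeans(tr[seq(2, nrow(tr), by = 2), , drop = FALSE])
    list(odd = erp_signal(times, odd), even = erp_signal(times, even))
  })
  template <- grand_average(study$erps)
  lat <- function(part) {
    extract_latencies(purrr::map(halves, part), method = method,
                      template = template, window = window,
                      weight_fn = weight_fn, penalty = penalty)$latency_ms
  }
  l_odd <- lat("odd")
  l_even <- lat("even")
  list(
    alpha = two_part_alpha(l_odd, l_even, standardize = standardize),
    halves = tibble(
      id = names(study$trials), latency_odd = l_odd, latency_even = l_even
    )
  )
}
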