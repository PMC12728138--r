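# shared fixtures: everything is generated in code, nothing on disk

default_grid <- function() seq(-200, 998, by = 2)

gaussian_sig <- function(center, sd, amp = 1, times = default_grid()) {
  erp_signal(times, amp * exp(-(times - center)^2 / (2 * sd^2)))
}

# smooth band-limited test signal (sum of low-frequency cosines)
smooth_sig <- function(times = default_grid(), seed = 1) {
  withr::with_seed(seed, {
    coef <- rnorm(4)
    vals <- coef[1] * cos(2 * pi * times / 1200) +
      coef[2] * sin(2 * pi * times / 800) +
      coef[3] * cos(2 * pi * times / 500) +
      coef[4] * sin(2 * pi * times / 350)
    erp_signal(times, vals)
  })
}

default_template <- function() make_population_template()

# a zero-amplitude template: used to build pure-noise subjects
null_template <- function() {
  make_population_template(erp_component(370, 80, 0))
}

# dense-integration oracle: resample at 0.05 ms with linear interpolation,
# accumulate, and return the time where the running sum crosses frac * total
dense_area_oracle <- function(times, vals, frac = 0.5) {
  fine <- seq(times[1], times[length(times)], by = 0.05)
  fv <- approx(times, vals, xout = fine)$y
  cs <- cumsum(fv)
  if (max(cs) <= 0) return(NA_real_)
  fine[which(cs >= frac * max(cs))[1]]
}

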