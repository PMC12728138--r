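test_that("peak latency finds a clean Gaussian peak and rejects ramps", {
  sig <- gaussian_sig(400, 60, amp = 8)
  expect_equal(peak_latency(sig), 400, tolerance = 2)

  ramp <- erp_signal(default_grid(), pmax(0, 0.01 * default_grid()))
  expect_true(is.na(peak_latency(ramp, window = c(250, 900))))
})

test_that("peak latency equals an exhaustive scan applying the rule literally", {
  for (i in 1:50) {
    sig <- withr::with_seed(i, {
      g <- default_grid()
      erp_signal(g, 6 * exp(-(g - (320 + 10 * i %% 150))^2 / (2 * 50^2)) +
                   rnorm(length(g), sd = 1.5))
    })
    got <- peak_latency(sig, window = c(250, 900))
    # literal scan oracle
    t <- sig$time
    v <- sig$amplitude
    best_v <- -Inf
    best_t <- NA_real_
    for (j in seq_along(t)) {
      if (t[j] < 250 || t[j] > 900 || j < 4 || j > length(t) - 3) next
      if (v[j] > mean(v[(j - 3):(j - 1)]) && v[j] > mean(v[(j + 1):(j + 3)]) &&
          v[j] > best_v) {
        best_v <- v[j]
        best_t <- t[j]
      }
    }
    expect_identical(got, best_t)
  }
})

test_that("50% area latency bisects a symmetric triangle and handles negatives", {
  g <- default_grid()
  tri <- erp_signal(g, pmax(0, 5 - abs(g - 450) / 20))
  expect_equal(area_latency(tri, c(250, 700)), 450, tolerance = 1)

  neg <- erp_signal(g, rep(-1, length(g)))
  expect_true(is.na(area_latency(neg, c(250, 700))))
})

test_that("area latency agrees with a dense-integration oracle", {
  for (i in 1:20) {
    sig <- withr::with_seed(100 + i, {
      g <- default_grid()
      erp_signal(g, abs(cumsum(rnorm(length(g), sd = 0.3))) +
                   4 * exp(-(g - 420)^2 / (2 * 70^2)))
    })
    idx <- sig$time >= 250 & sig$time <= 700
    oracle <- dense_area_oracle(sig$time[idx], pmax(sig$amplitude[idx], 0))
    expect_equal(area_latency(sig, c(250, 700)), oracle, tolerance = 1)
  }
})

test_that("the 50%-amplitude relative baseline keeps symmetric latencies", {
  sig <- gaussian_sig(400, 60, amp = 8)
  expect_equal(liesefeld_a_latency(sig, c(250, 700)), 400, tolerance = 1)

  g <- default_grid()
  box <- erp_signal(g, ifelse(g >= 300 & g <= 500, 10, 0))
  expect_equal(liesefeld_a_latency(box, c(250, 700)), 400, tolerance = 1)

  # all-negative window is missing
  trough <- gaussian_sig(400, 60, amp = -8)
  expect_true(is.na(liesefeld_a_latency(trough, c(250, 700))))
})

test_that("relative-baseline latency matches a transform-then-integrate oracle", {
  g <- default_grid()
  bimodal <- erp_signal(
    g,
    10 * exp(-(g - 420)^2 / (2 * 40^2)) + 3 * exp(-(g - 600)^2 / (2 * 25^2))
  )
  idx <- bimodal$time >= 250 & bimodal$time <= 700
  v <- bimodal$amplitude[idx]
  m <- max(v)
  oracle <- dense_area_oracle(bimodal$time[idx], pmax(v - 0.5 * m, 0))
  expect_equal(liesefeld_a_latency(bimodal, c(250, 700)), oracle, tolerance = 1)
})

test_that("crossing-constrained latency ignores activity outside the component", {
  sig <- gaussian_sig(400, 50, amp = 10)
  alone <- liesefeld_b_latency(sig, c(250, 900))
  expect_equal(alone, 400, tolerance = 1)

  g <- default_grid()
  with_bump <- erp_signal(
    g, 10 * exp(-(g - 400)^2 / (2 * 50^2)) + 6 * exp(-(g - 850)^2 / (2 * 20^2))
  )
  expect_equal(liesefeld_b_latency(with_bump, c(250, 900)), alone,
               tolerance = 1)
})

test_that("crossing-constrained latency clamps when a side never crosses", {
  g <- default_grid()
  ramp <- erp_signal(g, pmax(0, (g - 250) / 100))
  got <- liesefeld_b_latency(ramp, c(250, 700))
  # oracle: ramp peaks at the window edge; left crossing at 30% of peak,
  # right side clamped to the window bound
  idx <- ramp$time >= 250 & ramp$time <= 700
  t <- ramp$time[idx]
  v <- ramp$amplitude[idx]
  beta <- 0.3 * max(v)
  keep <- v >= beta
  oracle <- dense_area_oracle(t[keep], pmax(v[keep] - beta, 0))
  expect_equal(got, oracle, tolerance = 1)
})

test_that("all extractors are equivariant to amplitude scaling", {
  sig <- withr::with_seed(5, {
    g <- default_grid()
    erp_signal(g, 7 * exp(-(g - 430)^2 / (2 * 55^2)) + rnorm(length(g), sd = 0.5))
  })
  for (f in list(peak_latency, area_latency, liesefeld_a_latency,
                 liesefeld_b_latency)) {
    l1 <- f(sig, c(250, 700))
    l2 <- f(scale_amplitude(sig, 3.7), c(250, 700))
    expect_equal(l2, l1)
  }
})

test_that("all extractors track an on-grid translation of the component", {
  g <- default_grid()
  make_at <- function(center) gaussian_sig(center, 35, amp = 9, times = g)
  for (f in list(peak_latency, area_latency, liesefeld_a_latency,
                 liesefeld_b_latency)) {
    l1 <- f(make_at(400), c(250, 700))
    l2 <- f(make_at(440), c(250, 700))
    expect_equal(l2 - l1, 40, tolerance = 1)
  }
})

test_that("negative-polarity extraction mirrors the positive case", {
  sig <- gaussian_sig(400, 50, amp = -8)
  expect_equal(peak_latency(sig, c(250, 700), polarity = "negative"), 400,
               tolerance = 2)
  expect_equal(liesefeld_a_latency(sig, c(250, 700), polarity = "negative"),
               400, tolerance = 1)
})

test_that("area variants coincide for a symmetric supra-baseline component", {
  # for a symmetric pulse the baseline subtraction cannot move the midpoint
  sig <- gaussian_sig(450, 40, amp = 10)
  w <- c(300, 600)
  expect_equal(liesefeld_a_latency(sig, w), area_latency(sig, w), tolerance = 1)
  expect_equal(liesefeld_b_latency(sig, w), area_latency(sig, w), tolerance = 1)
})
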