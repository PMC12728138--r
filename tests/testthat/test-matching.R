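test_that("the MINSQ objective equals a hand-computed sum on tiny inputs", {
  times <- c(0, 1, 2, 3)
  tmpl <- erp_signal(times, c(1, 2, 0, 0))
  flat <- erp_signal(times, c(0, 0, 0, 0))
  w <- rep(1, 4)
  expect_equal(minsq_objective(flat, tmpl, a = 1, b = 1, weights = w), 5)
  expect_equal(minsq_objective(tmpl, tmpl, a = 1, b = 1, weights = w), 0)
})

test_that("the MINSQ objective matches a literal loop-summation oracle", {
  withr::with_seed(42, {
    times <- seq(-20, 178, by = 2)
    tmpl <- erp_signal(times, cumsum(rnorm(100)) / 5)
    sig <- erp_signal(times, cumsum(rnorm(100)) / 5)
    w <- runif(100)
    for (b in c(1, 1.15)) {
      a <- 1.3
      got <- minsq_objective(sig, tmpl, a = a, b = b, weights = w)
      # oracle: transform via the (separately tested) stretch, then loop
      tt <- scale_amplitude(stretch_signal(tmpl, b), a)
      acc <- 0
      wsum <- 0
      for (i in seq_along(times)) {
        if (tt$valid[i]) {
          acc <- acc + w[i] * (tt$amplitude[i] - sig$amplitude[i])^2
          wsum <- wsum + w[i]
        }
      }
      oracle <- acc * sum(w) / wsum
      expect_equal(got, oracle, tolerance = 1e-10)
    }
  })
})

test_that("weighted correlation transcribes the weighted-covariance formula", {
  withr::with_seed(7, {
    x <- rnorm(50)
    y <- 0.5 * x + rnorm(50)
    w <- runif(50)
    got <- weighted_correlation(x, y, w)
    # independent explicit summation of the printed formula
    mx <- sum(w * x) / sum(w)
    my <- sum(w * y) / sum(w)
    cxy <- sum(w * (x - mx) * (y - my)) / sum(w)
    cxx <- sum(w * (x - mx)^2) / sum(w)
    cyy <- sum(w * (y - my)^2) / sum(w)
    expect_equal(got, cxy / sqrt(cxx * cyy), tolerance = 1e-12)
    # reduces to Pearson under uniform weights
    expect_equal(weighted_correlation(x, y, rep(1, 50)), cor(x, y),
                 tolerance = 1e-12)
    # self-correlation is exactly 1
    expect_equal(weighted_correlation(x, x, w), 1, tolerance = 1e-12)
  })
  expect_error(weighted_correlation(rep(1, 5), rnorm(5), rep(1, 5)),
               class = "erplatency_degenerate")
})

test_that("the stretch penalty applies exactly outside (2/3, 1.5)", {
  expect_identical(apply_penalty(7.3, 1.0, "minimize"), 7.3)
  expect_identical(apply_penalty(7.3, 0.99, "minimize"), 7.3)
  expect_identical(apply_penalty(7.3, 1.49, "minimize"), 7.3)
  expect_equal(apply_penalty(1.0, 1.5, "minimize"), exp(1.5))
  expect_equal(apply_penalty(2.0, 0.5, "minimize"), 2 * exp(2))
  expect_equal(apply_penalty(1.0, 2 / 3, "minimize"), exp(1.5))
  expect_equal(apply_penalty(1.0, 1.8, "minimize"), exp(1.8))
  # maximized objectives are divided so the penalty always hurts
  expect_equal(apply_penalty(0.9, 1.6, "maximize"), 0.9 / exp(1.6))
  expect_equal(apply_penalty(0.9, 0.6, "maximize"), 0.9 / exp(1 / 0.6))
})

test_that("fit screening rejects strictly below the cutoff", {
  tmpl <- default_template()
  fit <- fit_template(tmpl, tmpl)
  fake <- function(r) {
    f <- fit
    f$fit_r <- r
    screen_fit(f, 0.3)
  }
  expect_false(fake(0.29)$valid)
  expect_identical(fake(0.29)$reject_reason, "low_fit")
  expect_true(fake(0.30)$valid)
  f <- fit
  f$fit_r <- -0.99
  expect_true(screen_fit(f, -1)$valid)
})

test_that("self-match recovers the identity transform", {
  tmpl <- default_template()
  fit <- fit_template(tmpl, tmpl)
  expect_equal(fit$b_opt, 1, tolerance = 0.01)
  expect_equal(fit$a_opt, 1, tolerance = 0.01)
  expect_gt(fit$fit_r, 0.999)
  expect_equal(fit$latency_ms, fit$l_ga, tolerance = 0.5)
  expect_true(fit$valid)
})

test_that("MINSQ recovers a known stretch and amplitude scaling", {
  tmpl <- default_template()
  sig <- scale_amplitude(stretch_signal(tmpl, 0.9), 1.2)
  fit <- fit_template(sig, tmpl)
  expect_equal(fit$b_opt, 0.90, tolerance = 0.01)
  expect_equal(fit$a_opt, 1.20, tolerance = 0.02)
})

test_that("the multistart optimum beats a dense grid search", {
  tmpl <- default_template()
  withr::with_seed(31, {
    subj <- generate_subject_erp(tmpl, b_true = 1.12, a_true = 0.8,
                                 noise_sd = 3, n_trials = 30, seed = 31)$erp
  })
  w <- make_weights(tmpl, c(250, 700), "normalized")$weight
  prep <- erplatency:::prepare_match(tmpl, w)
  s <- subj$amplitude
  sv <- subj$valid

  # MINSQ vs 41 x 41 grid over (a, b)
  cfg <- match_config("minsq")
  fit <- fit_template(subj, tmpl, cfg)
  grid_vals <- outer(
    seq(0.2, 20, length.out = 41), seq(0.3, 2, length.out = 41),
    Vectorize(function(a, b) {
      apply_penalty(erplatency:::minsq_value(s, sv, prep, a, b), b, "minimize")
    })
  )
  expect_lte(fit$objective_penalized, min(grid_vals) + 1e-6)

  # MAXCOR vs 41-point line search over b
  cfg2 <- match_config("maxcor")
  fit2 <- fit_template(subj, tmpl, cfg2)
  line_vals <- vapply(seq(0.3, 2, length.out = 41), function(b) {
    apply_penalty(erplatency:::maxcor_value(s, sv, prep, b), b, "maximize")
  }, numeric(1))
  expect_gte(fit2$objective_penalized, max(line_vals, na.rm = TRUE) - 1e-6)
})

test_that("MAXCOR is invariant to amplitude scaling of the signal", {
  tmpl <- default_template()
  subj <- generate_subject_erp(tmpl, b_true = 0.92, noise_sd = 2,
                               n_trials = 40, seed = 9)$erp
  cfg <- match_config("maxcor")
  f1 <- fit_template(subj, tmpl, cfg)
  for (c_amp in c(0.25, 4)) {
    f2 <- fit_template(scale_amplitude(subj, c_amp), tmpl, cfg)
    expect_equal(f2$b_opt, f1$b_opt, tolerance = 1e-6)
    expect_equal(f2$fit_r, f1$fit_r, tolerance = 1e-9)
  }
})

test_that("transforming the template and rescaling the signal agree", {
  # the matcher's forward direction vs the inverse direction (roles swapped,
  # stretch factor inverted) must land on the same transform
  tmpl <- default_template()
  cfg <- match_config("minsq", weight_fn = "tukey25")
  n_checked <- 0
  for (i in 1:30) {
    subj <- generate_subject_erp(tmpl, b_true = runif(1, 0.85, 1.2),
                                 a_true = runif(1, 0.8, 1.3), noise_sd = 1.5,
                                 n_trials = 60, seed = 500 + i)$erp
    fwd <- fit_template(subj, tmpl, cfg)
    inv <- fit_template(tmpl, subj, cfg)
    if (fwd$valid && inv$valid) {
      expect_equal(fwd$b_opt, 1 / inv$b_opt, tolerance = 0.01)
      expect_equal(fwd$fit_r, inv$fit_r, tolerance = 0.005)
      n_checked <- n_checked + 1
    }
  }
  expect_gt(n_checked, 25)
})

test_that("the penalty pulls mass out of the extreme-stretch tails", {
  tmpl <- default_template()
  outside <- function(penalty) {
    b <- vapply(1:25, function(i) {
      subj <- generate_subject_erp(tmpl, b_true = 1, a_true = 1,
                                   noise_sd = 12, n_trials = 4,
                                   seed = 900 + i)$erp
      fit_template(subj, tmpl, match_config("minsq", penalty = penalty))$b_opt
    }, numeric(1))
    sum(b <= 0.5 | b >= 1.9)
  }
  expect_lte(outside(TRUE), outside(FALSE))
})

test_that("degenerate signals are flagged, not fatal", {
  tmpl <- default_template()
  flat <- erp_signal(tmpl$time, rep(0, nrow(tmpl)))
  fit <- fit_template(flat, tmpl)
  expect_false(fit$valid)
  expect_identical(fit$reject_reason, "degenerate")
  expect_true(is.na(fit$fit_r))
})

test_that("latency estimates scale linearly under an on-grid stretch", {
  tmpl <- default_template()
  subj <- generate_subject_erp(tmpl, b_true = 1, noise_sd = 0.5,
                               n_trials = 40, seed = 77)$erp
  base <- fit_template(subj, tmpl)$latency_ms
  for (c_str in c(0.85, 1.15)) {
    lat <- fit_template(stretch_signal(subj, c_str), tmpl)$latency_ms
    expect_equal(lat, c_str * base, tolerance = 2 / base + 0.01)
  }
})
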