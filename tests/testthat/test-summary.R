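test_that("dominant period handles canonical series", {
  expect_equal(dominant_period(rep(3, 64)), 1)          # constant -> steady
  expect_equal(dominant_period(rep(c(10, 2), 50)), 2)   # Nyquist alternation
  expect_equal(dominant_period(sin(2 * pi * (1:512) / 32)), 32)
  # series within the steady band is classified as period 1
  expect_equal(dominant_period(100 + 0.01 * sin(2 * pi * (1:64) / 8),
                               tolerance = 0.1), 1)
  expect_error(dominant_period(1:5), "too short")
})

test_that("40-year sine over 500 years lands in the winning DFT bin", {
  x <- sin(2 * pi * (1:500) / 40)
  k <- dft_argmax(x) # direct O(N^2) oracle decides 500/12 vs 500/13
  expect_equal(dominant_period(x), 500 / k)
  expect_lt(abs(dominant_period(x) - 40), 4)
})

test_that("period detection matches the O(N^2) DFT oracle on random series", {
  set.seed(202)
  for (i in 1:60) {
    n <- sample(8:128, 1)
    x <- rnorm(n) + if (i %% 2) 3 * sin(2 * pi * (1:n) / sample(2:20, 1))
                    else 0
    expect_equal(dominant_period(x), n / dft_argmax(x))
  }
})

test_that("period detection ignores constant offsets", {
  set.seed(8)
  x <- rnorm(100) + sin(2 * pi * (1:100) / 10)
  expect_equal(dominant_period(x + 1e6), dominant_period(x))
})

test_that("summaries report window maxima and steadiness correctly", {
  tr <- data.frame(year = 1:300, J = 0, S = 1000, I = 0, F = 0, P = 1)
  tr$I[250] <- 5000
  s <- fb_summarize(tr, window = 300, steady_band = 1)
  expect_equal(s$max_I, 5000)
  expect_true(s$is_steady)                  # S constant
  expect_equal(s$dominant_period_I, 1)      # steady forces period 1
  # window restriction: spike outside the window is ignored
  s2 <- fb_summarize(tr, window = 40, steady_band = 1)
  expect_equal(s2$max_I, 0)
  expect_error(fb_summarize(tr, window = 0), "window")
  expect_error(fb_summarize(tr, window = 1000), "window")
  # beetle-free trajectory
  fx <- make_fixture("beetle_free")
  expect_equal(fb_summarize(fx$trajectory)$max_I, 0)
})

test_that("baseline outbreak regime is periodic, not steady", {
  fx <- make_fixture("fig3_point_det")
  s <- fb_summarize(fx$trajectory)
  expect_false(s$is_steady)
  expect_gt(s$dominant_period_I, 1) # recurrent outbreak pulses
  expect_gt(s$max_I, 500)
})

test_that("ensembles are reproducible, degenerate at sigma = 0, and consistent", {
  p0 <- fb_params(sigma_F = 0, sigma_I = 0, burn_in = 200, horizon = 120)
  e0 <- fb_ensemble(p0, n_reps = 5, seed_base = 1)
  expect_equal(e0$max_I_se, 0)  # identical replicates
  expect_equal(e0$mean_S_se, 0)

  p <- fb_params(burn_in = 300, horizon = 200)
  a <- fb_ensemble(p, n_reps = 10, seed_base = 5)
  b <- fb_ensemble(p, n_reps = 10, seed_base = 5)
  expect_identical(as.data.frame(a), as.data.frame(b))

  # Monte-Carlo consistency: halved ensembles agree within ~2 combined SE
  big <- fb_ensemble(p, n_reps = 60, seed_base = 100)
  small <- fb_ensemble(p, n_reps = 30, seed_base = 500)
  tol <- 2 * sqrt(big$max_I_se^2 + small$max_I_se^2)
  expect_lt(abs(big$max_I_mean - small$max_I_mean), max(tol, 1))

  # period averaging happens on the frequency scale
  expect_equal(big$period_I, 1 / big$freq_I_mean)
})
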