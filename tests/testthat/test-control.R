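test_that("class selection maximizes treated population with oldest-first ties", {
  expect_identical(select_classes(c(5, 1, 9, 9), 2), c(3L, 4L))
  expect_identical(select_classes(c(2, 2, 2), 2), c(2L, 3L)) # ties -> oldest
  expect_identical(select_classes(runif(10), 0), integer(0))
  expect_identical(select_classes(c(1, 2, 3), 3), 1:3)
  expect_error(select_classes(c(1, 2), 3), "'m'")
})

test_that("class selection matches brute-force subset enumeration", {
  set.seed(42)
  for (i in 1:200) {
    K <- sample(2:8, 1)
    j <- round(runif(K, 0, 10), sample(0:1, 1)) # coarse values force ties
    m <- sample(0:min(4, K), 1)
    sel <- select_classes(j, m)
    expect_length(sel, m)
    expect_equal(sum(j[sel]), brute_best_sum(j, m))
  }
})

test_that("tau = 0 or m = 0 policies are behavioural no-ops", {
  p <- fb_params(burn_in = 50, horizon = 100)
  base <- fb_simulate(p, seed = 9)
  for (pol in list(fb_policy("ftp", tau = 0, m = 8),
                   fb_policy("cbp", tau = 0.15, m = 0),
                   fb_policy("none"))) {
    tr <- fb_simulate(p, pol, seed = 9)
    expect_identical(tr$I, base$I)
    expect_identical(tr$F, base$F)
  }
})

test_that("interventions redistribute mass without creating or destroying it", {
  # deterministic conservation identity along whole managed runs
  for (pol in list(fb_policy("ftp", tau = 0.15, m = 8),
                   fb_policy("cbp", tau = 0.15, m = 8, period = 5),
                   fb_policy("ftp", tau = 1, m = 49))) {
    p <- fb_params(sigma_F = 0, sigma_I = 0, burn_in = 0, horizon = 500)
    tr <- fb_simulate(p, pol, seed = 1)
    idx <- 3:nrow(tr)
    tot <- tr$I[idx - 1] + tr$I[idx - 2] + tr$F[idx] + tr$J[idx] + tr$S[idx]
    expect_lt(max(abs(tot - p$T)) / p$T, 1e-9)
  }
})

test_that("thinning flattens the aging cohort and steadies maturation", {
  p <- fb_params(sigma_F = 0, sigma_I = 0)
  none <- fb_simulate(p, seed = 1, keep_ages = TRUE)
  ftp <- fb_simulate(p, fb_policy("ftp", tau = 0.15, m = 8), seed = 1,
                     keep_ages = TRUE)
  old <- (p$K %/% 2):p$K # the classes about to feed the susceptible pool
  peakiness <- function(tr) {
    ages <- attr(tr, "ages")[, old]
    mean(apply(ages, 1, function(a) max(a) / mean(a)))
  }
  # the traveling even-aged bump is eroded before it reaches maturity ...
  expect_lt(peakiness(ftp), peakiness(none))
  # ... so the flux of newly mature trees varies much less through time
  flux_cv <- function(tr) {
    jk <- attr(tr, "ages")[, p$K]
    sd(jk) / mean(jk)
  }
  expect_lt(flux_cv(ftp), 0.75 * flux_cv(none))
})

test_that("extreme annual thinning reduces outbreaks; quinquennial is intermediate", {
  p <- fb_params() # outbreak operating point, noise on
  seeds <- 1:12
  maxI <- function(pol) fb_ensemble(p, pol, seeds = seeds)$max_I_mean
  none <- maxI(NULL)
  annual <- maxI(fb_policy("ftp", tau = 0.15, m = 8, period = 1))
  quinq <- maxI(fb_policy("ftp", tau = 0.15, m = 8, period = 5))
  expect_lt(annual, none)
  # quinquennial sits between no control and annual control (generous band:
  # it must achieve some of the annual effect without overshooting it much)
  expect_lt(quinq, none)
  expect_gt(quinq, annual - 0.25 * (none - annual))
})
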