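#' Dominant period of a yearly series
#'
#' Detects the dominant cycle length by discrete Fourier transform: the mean
#' is removed, and the period is `N / k*` where `k*` is the index (over
#' frequencies `1..floor(N/2)` cycles per record) of the maximum-modulus DFT
#' coefficient. A series whose range `max - min` is within `tolerance` is
#' classified as a (stochastic) steady state and gets period 1. Ties in the
#' modulus are broken toward the lowest frequency.
#'
#' @param x numeric series sampled yearly, length at least 8.
#' @param tolerance steady-state band on `max(x) - min(x)`; default 0
#'   classifies only an exactly constant series as steady.
#' @return Period in years (`>= 1`); `N / k*` is generally non-integer.
#' @examples
#' dominant_period(rep(3, 64))                      # 1
#' dominant_period(sin(2 * pi * (1:512) / 32))      # 32
#' @export
dominant_period <- function(x, tolerance = 0) {
  n <- length(x)
  if (n < 8L) stop("series too short for period detection (need >= 8 years)",
                   call. = FALSE)
  if (any(!is.finite(x))) stop("non-finite values in series", call. = FALSE)
  if (max(x) - min(x) <= tolerance) return(1)
  z <- x - mean(x)
  mod <- Mod(fft(z))
  ks <- seq_len(n %/% 2L)
  k_star <- ks[which.max(mod[ks + 1L])]
  n / k_star
}

#' Summarise a trajectory window
#'
#' Computes the standard end-point summaries over the final `window` years
#' of a trajectory: the largest infested population (`max_I`), the largest
#' fire season (`max_F`), the time-average susceptible population
#' (`mean_S`), and the dominant periods of the infested and burned series.
#' The run is classified as a steady state when the susceptible series'
#' range is below `steady_band` (default `1e-3 * T`); steady runs report
#' period 1. Dominant frequencies (1/period, cycles per year) are reported
#' alongside so either convention can be mapped.
#'
#' @param traj an `fb_trajectory` (or data frame with columns `S`, `I`, `F`).
#' @param window number of final years to summarise; default all rows.
#' @param steady_band range threshold on the susceptible series for the
#'   steady-state classification.
#' @return One-row data frame of class `fb_summary` with fields `max_I`,
#'   `max_F`, `dominant_period_I`, `dominant_period_F`, `freq_I`, `freq_F`,
#'   `mean_S`, `is_steady`.
#' @export
fb_summarize <- function(traj, window = nrow(traj), steady_band = NULL) {
  if (is.null(window) || window < 1L)
    stop("invalid 'window': need at least one year", call. = FALSE)
  if (window > nrow(traj))
    stop("invalid 'window': longer than the trajectory", call. = FALSE)
  if (is.null(steady_band)) {
    p <- attr(traj, "params")
    steady_band <- if (!is.null(p)) 1e-3 * p$T else 0
  }
  w <- traj[(nrow(traj) - window + 1L):nrow(traj), , drop = FALSE]
  is_steady <- (max(w$S) - min(w$S)) < steady_band
  if (is_steady || window < 8L) {
    per_I <- per_F <- 1
  } else {
    per_I <- dominant_period(w$I, tolerance = steady_band)
    per_F <- dominant_period(w$F, tolerance = steady_band)
  }
  out <- data.frame(max_I = max(w$I), max_F = max(w$F),
                    dominant_period_I = per_I, dominant_period_F = per_F,
                    freq_I = 1 / per_I, freq_F = 1 / per_F,
                    mean_S = mean(w$S), is_steady = is_steady)
  class(out) <- c("fb_summary", "data.frame")
  out
}

#' Ensemble of independent realizations
#'
#' Runs `n_reps` independent realizations (seeds `seed_base`,
#' `seed_base + 1`, ... unless explicit `seeds` are given), summarises each
#' with [fb_summarize()], and returns the ensemble mean and standard error
#' of each summary. Replicate periods are averaged on the frequency scale
#' (steady replicates contribute frequency 1) and the mean frequency is
#' inverted back to a period.
#'
#' @param params an [fb_params()] object.
#' @param policy an [fb_policy()] or `NULL`.
#' @param n_reps number of realizations.
#' @param seed_base first replicate seed; replicate `i` uses
#'   `seed_base + i - 1`.
#' @param seeds optional explicit integer seeds (overrides `seed_base`);
#'   reusing the same seeds across policies gives paired, common-random-number
#'   comparisons.
#' @param window passed to [fb_summarize()].
#' @param keep_reps if `TRUE`, per-replicate summaries are attached as
#'   `attr(x, "reps")`.
#' @return One-row data frame of class `fb_ensemble`: `*_mean` and `*_se`
#'   for `max_I`, `max_F`, `mean_S` and the dominant frequencies, plus
#'   `period_I`, `period_F` (inverse mean frequencies) and `n_reps`.
#' @examples
#' p <- fb_params(horizon = 100, burn_in = 200)
#' fb_ensemble(p, n_reps = 4, seed_base = 1)
#' @export
fb_ensemble <- function(params, policy = NULL, n_reps = 100,
                        seed_base = params$seed, seeds = NULL,
                        window = NULL, keep_reps = FALSE) {
  if (n_reps < 1) stop("'n_reps' must be >= 1", call. = FALSE)
  if (is.null(seeds)) seeds <- seed_base + seq_len(n_reps) - 1L
  n_reps <- length(seeds)
  reps <- vector("list", n_reps)
  for (i in seq_len(n_reps)) {
    tr <- fb_simulate(params, policy, seed = seeds[i])
    s <- fb_summarize(tr, window = if (is.null(window)) nrow(tr) else window)
    s$seed <- seeds[i]
    reps[[i]] <- s
  }
  reps <- do.call(rbind, reps)
  m <- function(v) mean(v)
  se <- function(v) if (n_reps > 1) sd(v) / sqrt(n_reps) else 0
  out <- data.frame(
    max_I_mean = m(reps$max_I), max_I_se = se(reps$max_I),
    max_F_mean = m(reps$max_F), max_F_se = se(reps$max_F),
    mean_S_mean = m(reps$mean_S), mean_S_se = se(reps$mean_S),
    freq_I_mean = m(reps$freq_I), freq_I_se = se(reps$freq_I),
    freq_F_mean = m(reps$freq_F), freq_F_se = se(reps$freq_F),
    n_reps = n_reps)
  out$period_I <- 1 / out$freq_I_mean
  out$period_F <- 1 / out$freq_F_mean
  if (keep_reps) attr(out, "reps") <- reps
  class(out) <- c("fb_ensemble", "data.frame")
  out
}
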