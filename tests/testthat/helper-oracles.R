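# Independent, deliberately naive transcriptions of the model used as
# oracles. Loop-based, direct sums, no code shared with the package
# internals.

naive_severity <- function(F_history, kappa, T) {
  n <- length(F_history)
  s <- 0
  if (n > 0)
    for (i in seq_len(n)) s <- s + F_history[i] * exp(-kappa * (n - i))
  max(0, T - s)
}

# one annual update, written straight from the difference equations
naive_step <- function(state, params, policy = NULL, xi = 0, gamma = 0,
                       applying = FALSE) {
  p <- params
  K <- p$K
  j <- state$j
  P <- naive_severity(state$F_history, p$kappa, p$T)

  Jtot <- 0
  for (k in 1:K) Jtot <- Jtot + j[k]

  jn <- numeric(K)
  jn[1] <- p$d * Jtot + state$I_lag2 + state$F
  for (k in 2:K)
    jn[k] <- (1 - p$d) * j[k - 1] - (p$alpha1 / p$T) * P * j[k - 1]

  do_policy <- applying && !is.null(policy) && policy$mode != "none" &&
    policy$tau > 0 && policy$m > 0
  rem <- 0
  if (do_policy) {
    # pick the m largest classes of the advanced vector, ties to oldest
    picked <- integer(0)
    for (s in seq_len(min(policy$m, K))) {
      bi <- 0L
      for (k in 1:K)
        if (!(k %in% picked) && (bi == 0L || jn[k] >= jn[bi])) bi <- k
      picked <- c(picked, bi)
    }
    for (k in picked) {
      if (k >= 2) {
        rem <- rem + policy$tau * jn[k]
        jn[k] <- (1 - policy$tau) * jn[k]
      }
    }
    if (policy$mode == "ftp") jn[1] <- jn[1] + rem + p$sigma_F * gamma
  }

  mat <- state$S + (1 - p$d) * j[K]
  S_new <- mat - (state$I + (p$alpha2 / p$T) * P * state$I) -
    (p$alpha2 / p$T) * P * mat - p$sigma_F * gamma
  if (isTRUE(p$strict_noise_balance)) S_new <- S_new - p$sigma_I * xi

  I_new <- p$r1 * state$I * exp(-p$beta1 * (p$T - S_new)) -
    (p$alpha2 / p$T) * P * state$I + p$sigma_I * xi

  bsum <- 0
  for (k in 1:(K - 1)) bsum <- bsum + j[k]
  F_new <- P * ((p$alpha1 / p$T) * bsum + (p$alpha2 / p$T) * mat +
                  (p$alpha2 / p$T) * state$I) + p$sigma_F * gamma
  if (do_policy && policy$mode == "cbp") F_new <- F_new + rem

  jn[jn < 0] <- 0
  list(j = jn, S = max(0, S_new), I = max(0, I_new), F = max(0, F_new),
       I_lag1 = state$I, I_lag2 = state$I_lag1,
       F_history = c(state$F_history, max(0, F_new)))
}

# direct O(N^2) discrete-Fourier-sum argmax over frequencies 1..N/2
dft_argmax <- function(x) {
  n <- length(x)
  z <- x - sum(x) / n
  best <- -1
  bk <- 1L
  for (k in seq_len(n %/% 2)) {
    re <- 0
    im <- 0
    for (t in 0:(n - 1)) {
      ang <- -2 * pi * k * t / n
      re <- re + z[t + 1] * cos(ang)
      im <- im + z[t + 1] * sin(ang)
    }
    mod <- sqrt(re * re + im * im)
    if (mod > best) {
      best <- mod
      bk <- k
    }
  }
  bk
}

# best subset-of-size-m total population by full enumeration
brute_best_sum <- function(j, m) {
  if (m == 0) return(0)
  if (m == length(j)) return(sum(j))
  max(combn(seq_along(j), m, FUN = function(ix) sum(j[ix])))
}

# random parameter draw in a sane region (deterministic unless sigma given)
random_params <- function(sigma = 0) {
  fb_params(r1 = runif(1, 1.1, 2.5), beta1 = runif(1, 5e-6, 2e-5),
            d = runif(1, 0, 0.05), alpha1 = runif(1, 0, 0.03),
            alpha2 = runif(1, 0, 0.008), kappa = runif(1, 0.02, 0.5),
            T = runif(1, 1e3, 2e5), K = sample(3:30, 1),
            sigma_F = sigma, sigma_I = sigma,
            horizon = 50, burn_in = 0)
}

# parameter draw restricted to the self-limiting beetle regime (growth
# factor < 1 at mid-range susceptibility), where trajectories stay positive
# without clamping; used for multi-step conservation properties
regime_params <- function() {
  fb_params(r1 = runif(1, 1.2, 1.8), beta1 = runif(1, 1e-5, 2e-5),
            d = runif(1, 0, 0.05), alpha1 = runif(1, 0, 0.03),
            alpha2 = runif(1, 0, 0.008), kappa = runif(1, 0.05, 0.5),
            T = runif(1, 1e5, 2e5), K = sample(5:30, 1),
            sigma_F = 0, sigma_I = 0, horizon = 50, burn_in = 0)
}

# state in the same regime: mid-range juvenile load, small I and snag pools
regime_state <- function(params) {
  j <- runif(params$K)
  j <- j * runif(1, 0.25, 0.6) * params$T / sum(j)
  il1 <- runif(1, 0, 0.01 * params$T)
  il2 <- runif(1, 0, 0.01 * params$T)
  Fh <- runif(sample(1:5, 1), 0, 0.01 * params$T)
  st <- list(year = sample(0:100, 1), j = j,
             S = params$T - (il1 + il2 + Fh[length(Fh)] + sum(j)),
             I = runif(1, 0, 0.005 * params$T), I_lag1 = il1, I_lag2 = il2,
             F = Fh[length(Fh)], F_history = Fh)
  class(st) <- "fb_state"
  st
}

# random state satisfying the tree-equivalent identity
# T = I_lag1 + I_lag2 + F + sum(j) + S  (the current I is unconstrained)
random_state <- function(params) {
  repeat {
    j <- runif(params$K, 0, 0.5 * params$T / params$K)
    il1 <- runif(1, 0, 0.02 * params$T)
    il2 <- runif(1, 0, 0.02 * params$T)
    Fh <- runif(sample(1:5, 1), 0, 0.02 * params$T)
    F <- Fh[length(Fh)]
    S <- params$T - (il1 + il2 + F + sum(j))
    if (S > 0) break
  }
  st <- list(year = sample(0:100, 1), j = j, S = S,
             I = runif(1, 0, 0.02 * params$T), I_lag1 = il1, I_lag2 = il2,
             F = F, F_history = Fh)
  class(st) <- "fb_state"
  st
}

state_total <- function(st) st$I_lag1 + st$I_lag2 + st$F + sum(st$j) + st$S

rel_diff <- function(a, b) abs(a - b) / pmax(1, abs(a), abs(b))
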