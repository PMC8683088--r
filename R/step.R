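#' One annual update of the stand
#'
#' Advances an `fb_state` by one year using the model's difference
#' equations: fuel-memory fire severity, seedling recruitment from dead
#' juveniles, decayed snags and last year's burns, juvenile aging with fire
#' loss at rate `alpha1`, maturation into the susceptible pool with losses to
#' infestation and fire at rate `alpha2`, Ricker-type beetle growth
#' `r1 * I * exp(-beta1 * (T - S'))`, and burning of all living classes. The
#' same fire-noise draw `gamma` is debited from `S` and credited to `F`, so
#' fire noise transfers trees rather than creating them; the infestation
#' noise `xi` enters `I` only (unless `strict_noise_balance`).
#'
#' When a policy applies in this year, the juvenile vector is advanced first
#' and the `m` most-populated classes of the advanced vector are then each
#' thinned by the fraction `tau`; the removed mass is recycled to seedlings
#' (FTP, which then also carries the fire-noise term on the seedling class)
#' or diverted to the burned compartment (CBP). The seedling class has no
#' thinning equation -- selecting it treats nothing -- so either protocol
#' only redistributes tree-equivalents.
#'
#' This is the readable reference implementation of the update map;
#' [fb_simulate()] runs the same map in compiled code.
#'
#' @param state an `fb_state`, from [fb_init_state()] or a previous step.
#' @param params an [fb_params()] object.
#' @param policy an [fb_policy()] or `NULL` for no management.
#' @param xi,gamma standard-normal noise realizations for the year
#'   (infestation and fire respectively); default 0 gives the deterministic
#'   map.
#' @param applying whether the policy is applied this year; the default
#'   follows the schedule `year %% period == 0`.
#' @return The year `n + 1` state (`fb_state`), with attribute `n_clamped`
#'   counting compartments clamped at zero.
#' @export
fb_step <- function(state, params, policy = NULL, xi = 0, gamma = 0,
                    applying = NULL) {
  stopifnot(inherits(params, "fb_params"))
  for (f in c("j", "S", "I", "I_lag1", "I_lag2", "F"))
    if (any(!is.finite(state[[f]])))
      stop(sprintf("non-finite value in compartment '%s' at year %d", f,
                   state$year), call. = FALSE)

  p <- params
  K <- p$K
  j <- state$j
  if (length(j) != K) stop("state has wrong number of juvenile classes")

  P <- fire_severity(state$F_history, p$kappa, p$T)

  code <- policy_code(policy)
  if (is.null(applying))
    applying <- code != 0L && policy$tau > 0 && policy$m > 0 &&
      (state$year %% policy$period == 0L)
  applying <- isTRUE(applying) && code != 0L

  g <- (1 - p$d) - (p$alpha1 / p$T) * P
  J <- sum(j)

  jn <- numeric(K)
  jn[1] <- p$d * J + state$I_lag2 + state$F
  jn[2:K] <- g * j[1:(K - 1)]

  rem <- 0
  if (applying) {
    treated <- select_classes(jn, min(policy$m, K))
    treated <- treated[treated >= 2L] # seedling class only receives
    rem <- policy$tau * sum(jn[treated])
    jn[treated] <- jn[treated] * (1 - policy$tau)
    if (policy$mode == "ftp")
      jn[1] <- jn[1] + rem + p$sigma_F * gamma
  }

  mature_in <- state$S + (1 - p$d) * j[K]
  S_new <- mature_in - (state$I + (p$alpha2 / p$T) * P * state$I) -
    (p$alpha2 / p$T) * P * mature_in - p$sigma_F * gamma
  if (p$strict_noise_balance) S_new <- S_new - p$sigma_I * xi

  I_new <- p$r1 * state$I * exp(-p$beta1 * (p$T - S_new)) -
    (p$alpha2 / p$T) * P * state$I + p$sigma_I * xi

  F_new <- P * ((p$alpha1 / p$T) * sum(j[1:(K - 1)]) +
                  (p$alpha2 / p$T) * mature_in +
                  (p$alpha2 / p$T) * state$I) + p$sigma_F * gamma
  if (applying && policy$mode == "cbp") F_new <- F_new + rem

  n_clamped <- sum(jn < 0) + (S_new < 0) + (I_new < 0) + (F_new < 0)
  jn[jn < 0] <- 0
  S_new <- max(0, S_new)
  I_new <- max(0, I_new)
  F_new <- max(0, F_new)

  # retain only burn-history terms whose kernel weight can still matter
  hist <- c(state$F_history, F_new)
  if (p$kappa > 0) {
    keep <- ceiling(log(1e12) / p$kappa) + 1L
    if (length(hist) > keep) hist <- hist[(length(hist) - keep + 1L):length(hist)]
  }

  out <- list(year = state$year + 1L, j = jn, S = S_new, I = I_new,
              I_lag1 = state$I, I_lag2 = state$I_lag1, F = F_new,
              F_history = hist)
  class(out) <- "fb_state"
  attr(out, "n_clamped") <- n_clamped
  out
}
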