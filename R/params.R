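#' Model parameters
#'
#' Builds the full parameter set of the stand model. Defaults are the
#' baseline values of the underlying beetle--fire system: beetle fecundity
#' `r1 = 1.8`, search-failure rate `beta1 = 10.8e-6` per tree, juvenile
#' mortality `d = 0.01`, fuel decay `kappa = 0.1` per year, stand size
#' `T = 110000` tree-equivalents, `K = 50` juvenile age classes, and
#' environmental noise `sigma_F = sigma_I = 20` trees. The burning rates
#' `alpha1` (juveniles) and `alpha2` (adults) are the regime-controlling
#' parameters; their defaults are the reference operating point
#' `(0.02, 0.0025)` that produces recurrent beetle outbreaks.
#'
#' @param r1 yearly fecundity of beetles (dimensionless).
#' @param beta1 beetle search-failure rate (per tree).
#' @param d annual juvenile mortality probability.
#' @param alpha1 burning rate of juvenile trees (dimensionless).
#' @param alpha2 burning rate of adult (susceptible) trees.
#' @param kappa decay rate of fuel memory (per year).
#' @param T total stand size in tree-equivalents.
#' @param K number of juvenile age classes.
#' @param sigma_F std. deviation of fire noise (trees).
#' @param sigma_I std. deviation of infestation noise (trees).
#' @param horizon years in the analysis window returned by [fb_simulate()].
#' @param burn_in years simulated and discarded before the window.
#' @param seed default RNG seed for [fb_simulate()].
#' @param j0_frac fraction of the stand initially spread uniformly over the
#'   juvenile classes.
#' @param I0 initial infested population (trees).
#' @param strict_noise_balance if `TRUE`, the infestation noise added to `I`
#'   is debited from `S` so that stochastic runs conserve tree-equivalents
#'   exactly; the default `FALSE` applies the printed equations literally.
#'
#' @return An object of class `fb_params` (named list).
#' @examples
#' p <- fb_params(alpha1 = 0.01, alpha2 = 0.006)
#' p$alpha1
#' @export
fb_params <- function(r1 = 1.8, beta1 = 10.8e-6, d = 0.01,
                      alpha1 = 0.02, alpha2 = 0.0025, kappa = 0.1,
                      T = 110000, K = 50, sigma_F = 20, sigma_I = 20,
                      horizon = 500, burn_in = 1500, seed = 1L,
                      j0_frac = 0.04, I0 = 100,
                      strict_noise_balance = FALSE) {
  p <- list(r1 = r1, beta1 = beta1, d = d, alpha1 = alpha1,
            alpha2 = alpha2, kappa = kappa, T = T, K = as.integer(K),
            sigma_F = sigma_F, sigma_I = sigma_I,
            horizon = as.integer(horizon), burn_in = as.integer(burn_in),
            seed = as.integer(seed), j0_frac = j0_frac, I0 = I0,
            strict_noise_balance = isTRUE(strict_noise_balance))
  validate_params(p)
  class(p) <- "fb_params"
  p
}

validate_params <- function(p) {
  chk <- function(ok, field, msg) {
    if (!ok) stop(sprintf("invalid parameter '%s': %s", field, msg),
                  call. = FALSE)
  }
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  for (f in c("r1", "beta1", "d", "alpha1", "alpha2", "kappa", "T",
              "sigma_F", "sigma_I", "j0_frac", "I0"))
    chk(num1(p[[f]]) && p[[f]] >= 0, f, "must be a single non-negative number")
  chk(p$d <= 1, "d", "mortality is a probability, must be <= 1")
  chk(p$T > 0, "T", "stand size must be positive")
  chk(p$K >= 2, "K", "need at least two juvenile age classes")
  chk(p$horizon >= 1, "horizon", "analysis window must be >= 1 year")
  chk(p$burn_in >= 0, "burn_in", "burn-in must be >= 0 years")
  chk(p$j0_frac <= 1, "j0_frac", "must be a fraction")
  invisible(p)
}

#' @export
print.fb_params <- function(x, ...) {
  cat("<fb_params> fire-beetle stand model parameters\n")
  cat(sprintf("  stand T = %g tree-equivalents, K = %d juvenile classes\n",
              x$T, x$K))
  cat(sprintf("  beetle: r1 = %g, beta1 = %g; juvenile mortality d = %g\n",
              x$r1, x$beta1, x$d))
  cat(sprintf("  fire: alpha1 = %g, alpha2 = %g, kappa = %g\n",
              x$alpha1, x$alpha2, x$kappa))
  cat(sprintf("  noise: sigma_F = %g, sigma_I = %g%s\n", x$sigma_F,
              x$sigma_I,
              if (x$strict_noise_balance) " (strict conservation)" else ""))
  cat(sprintf("  run: burn_in = %d + horizon = %d years, seed = %d\n",
              x$burn_in, x$horizon, x$seed))
  invisible(x)
}

#' Management policy (FTP / CBP)
#'
#' Describes a thinning-type intervention: every `period` years, a fraction
#' `tau` of the trees advancing into each of the `m` most-populated juvenile
#' age classes is removed. Under the forest thinning protocol (`"ftp"`) the
#' removed trees re-enter the youngest juvenile class as seedlings; under
#' the controlled burning protocol (`"cbp"`) they are diverted to the burned
#' compartment. Either way the intervention only redistributes
#' tree-equivalents, never creates or destroys them.
#'
#' @param mode one of `"none"`, `"ftp"`, `"cbp"`.
#' @param tau removal fraction per treated class, in `[0, 1]`.
#' @param m number of treated age classes (0 disables the policy).
#' @param period years between applications (1 = annual, 5 = quinquennial).
#' @return An object of class `fb_policy`.
#' @examples
#' fb_policy("ftp", tau = 0.15, m = 8)
#' @export
fb_policy <- function(mode = c("none", "ftp", "cbp"), tau = 0, m = 0,
                      period = 1) {
  mode <- match.arg(tolower(mode[1L]), c("none", "ftp", "cbp"))
  if (!is.numeric(tau) || length(tau) != 1L || is.na(tau) ||
      tau < 0 || tau > 1)
    stop("invalid policy 'tau': removal fraction must lie in [0, 1]",
         call. = FALSE)
  if (!is.numeric(m) || length(m) != 1L || is.na(m) || m < 0 ||
      m != round(m))
    stop("invalid policy 'm': must be a non-negative integer", call. = FALSE)
  if (!is.numeric(period) || length(period) != 1L || is.na(period) ||
      period < 1 || period != round(period))
    stop("invalid policy 'period': must be an integer >= 1", call. = FALSE)
  pol <- list(mode = mode, tau = tau, m = as.integer(m),
              period = as.integer(period))
  class(pol) <- "fb_policy"
  pol
}

#' @export
print.fb_policy <- function(x, ...) {
  if (x$mode == "none" || x$tau == 0 || x$m == 0) {
    cat("<fb_policy> no management\n")
  } else {
    cat(sprintf("<fb_policy> %s: remove tau = %g from the m = %d largest juvenile classes every %d year(s)\n",
                toupper(x$mode), x$tau, x$m, x$period))
  }
  invisible(x)
}

policy_code <- function(policy) {
  if (is.null(policy)) return(0L)
  switch(policy$mode, none = 0L, ftp = 1L, cbp = 2L)
}

policy_label <- function(policy) {
  if (is.null(policy) || policy$mode == "none" || policy$tau == 0 ||
      policy$m == 0) return("none")
  sprintf("%s_tau%g_m%d_p%d", policy$mode, policy$tau, policy$m,
          policy$period)
}
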