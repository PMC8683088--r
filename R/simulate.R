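#' Simulate the stand model
#'
#' Runs `burn_in + horizon` annual updates from the default initial state
#' (see [fb_init_state()]) and returns the post-burn-in window as a yearly
#' trajectory. The per-year noise draws come from R's RNG in a fixed order
#' (infestation draw, then fire draw), so a seed fully determines the
#' trajectory.
#'
#' @param params an [fb_params()] object.
#' @param policy an [fb_policy()] or `NULL`; the policy schedule counts years
#'   from the start of the burn-in, so equilibria reflect sustained
#'   management.
#' @param seed integer RNG seed; defaults to `params$seed`.
#' @param keep_ages if `TRUE`, the full juvenile age distribution of each
#'   window year is kept in `attr(x, "ages")` (horizon x K matrix).
#' @return A data frame of class `fb_trajectory` with columns
#'   `year, J, S, I, F, P` (one row per window year; `year` counts from the
#'   start of the run), and attributes `params`, `policy`, `seed`,
#'   `n_clamped` and optionally `ages`.
#' @examples
#' p <- fb_params(horizon = 100, burn_in = 200)
#' tr <- fb_simulate(p, seed = 42)
#' head(tr)
#' @export
fb_simulate <- function(params, policy = NULL, seed = params$seed,
                        keep_ages = FALSE) {
  stopifnot(inherits(params, "fb_params"))
  if (!is.null(policy) && !inherits(policy, "fb_policy"))
    stop("'policy' must be an fb_policy or NULL", call. = FALSE)
  if (params$horizon <= 0)
    stop("invalid parameter 'horizon': must be positive", call. = FALSE)
  if (!is.null(policy) && policy$m > params$K)
    stop(sprintf("invalid policy 'm': cannot exceed K = %d", params$K),
         call. = FALSE)

  st <- fb_init_state(params)
  n_total <- params$burn_in + params$horizon
  pol <- if (is.null(policy)) fb_policy("none") else policy

  set.seed(as.integer(seed))
  res <- sim_engine(n_total, st$j, st$S, st$I, st$I_lag1, st$I_lag2, st$F,
                    params$r1, params$beta1, params$d, params$alpha1,
                    params$alpha2, params$kappa, params$T, params$sigma_F,
                    params$sigma_I, policy_code(pol), pol$tau, pol$m,
                    pol$period, params$strict_noise_balance, keep_ages)

  win <- (params$burn_in + 1L):n_total
  out <- data.frame(year = win, J = res$J[win], S = res$S[win],
                    I = res$I[win], F = res$F[win], P = res$P[win])
  attr(out, "params") <- params
  attr(out, "policy") <- pol
  attr(out, "seed") <- as.integer(seed)
  attr(out, "n_clamped") <- res$n_clamped
  if (keep_ages) attr(out, "ages") <- res$ages[win, , drop = FALSE]
  class(out) <- c("fb_trajectory", "data.frame")
  out
}

#' @export
print.fb_trajectory <- function(x, ...) {
  p <- attr(x, "params")
  pol <- attr(x, "policy")
  cat(sprintf("<fb_trajectory> %d years (post burn-in), seed %d\n",
              nrow(x), attr(x, "seed")))
  cat(sprintf("  alpha1 = %g, alpha2 = %g, policy: %s\n", p$alpha1,
              p$alpha2, policy_label(pol)))
  cat(sprintf("  max I = %.1f, max F = %.1f, mean S = %.1f\n",
              max(x$I), max(x$F), mean(x$S)))
  invisible(x)
}

#' @export
summary.fb_trajectory <- function(object, ...) {
  fb_summarize(object, ...)
}

#' Plot a simulated trajectory
#'
#' Draws the susceptible, infested and burned yearly series, plus the final
#' juvenile age distribution when the trajectory was simulated with
#' `keep_ages = TRUE`.
#'
#' @param x an `fb_trajectory`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.fb_trajectory <- function(x, ...) {
  has_ages <- !is.null(attr(x, "ages"))
  op <- par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  on.exit(par(op))
  if (has_ages) {
    ages <- attr(x, "ages")
    barplot(ages[nrow(ages), ], names.arg = seq_len(ncol(ages)),
            xlab = "juvenile age class", ylab = "trees",
            main = "final age distribution", border = NA)
  } else {
    plot(x$year, x$J, type = "l", xlab = "year", ylab = "juveniles J",
         main = "juvenile total", ...)
  }
  plot(x$year, x$S, type = "l", xlab = "year", ylab = "susceptible S",
       main = "mature trees", ...)
  plot(x$year, x$I, type = "l", xlab = "year", ylab = "infested I",
       main = "beetle outbreaks", ...)
  plot(x$year, x$F, type = "l", xlab = "year", ylab = "burned F",
       main = "fire seasons", ...)
  invisible(x)
}
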