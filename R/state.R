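#' Fire severity from the fuel-memory kernel
#'
#' Severity of a potential fire season, defined as the stand size minus an
#' exponentially decaying sum of past burned-tree counts:
#' `P_n = max(0, T - sum_i F_i * exp(-kappa * (n - i)))`. Large `kappa`
#' forgets past burns quickly; with no past fires the whole stand is
#' available fuel and `P_n = T`.
#'
#' @param F_history numeric vector of burned-tree counts for years
#'   `1..length(F_history)`; may be empty.
#' @param kappa fuel decay rate (per year, `>= 0`).
#' @param T stand size in tree-equivalents (`> 0`).
#' @param n year at which severity is evaluated; defaults to the last year
#'   of the history, so the most recent burn enters at full weight.
#' @return severity in tree-equivalents, within `[0, T]`.
#' @examples
#' fire_severity(numeric(0), kappa = 0.1, T = 110000)   # untouched stand
#' fire_severity(1000, kappa = 0.1, T = 110000, n = 2)  # one year after a burn
#' @export
fire_severity <- function(F_history, kappa, T,
                          n = length(F_history)) {
  if (!is.numeric(kappa) || length(kappa) != 1L || is.na(kappa) || kappa < 0)
    stop("invalid parameter 'kappa': decay rate must be >= 0", call. = FALSE)
  if (!is.numeric(T) || length(T) != 1L || is.na(T) || T <= 0)
    stop("invalid parameter 'T': stand size must be > 0", call. = FALSE)
  len <- length(F_history)
  if (len == 0L) return(T)
  if (n < len)
    stop("'n' must be at least the length of the burn history", call. = FALSE)
  w <- exp(-kappa * (n - seq_len(len)))
  max(0, min(T, T - sum(F_history * w)))
}

#' Initial stand state
#'
#' Builds the year-0 state used by [fb_simulate()]: a fraction `j0_frac` of
#' the stand spread uniformly over the `K` juvenile classes, `I0` currently
#' infested trees, empty snag lags and burn history, and the susceptible
#' pool taking up the remainder so that the tree-equivalent identity
#' `T = I_lag1 + I_lag2 + F + J + S` holds exactly from the first year.
#' The burn-in discards any dependence on this choice.
#'
#' @param params an [fb_params()] object.
#' @return A list of class `fb_state` with fields `year`, `j`, `S`, `I`,
#'   `I_lag1`, `I_lag2`, `F`, `F_history`.
#' @export
fb_init_state <- function(params) {
  stopifnot(inherits(params, "fb_params"))
  j <- rep(params$j0_frac * params$T / params$K, params$K)
  st <- list(year = 0L, j = j, S = params$T - sum(j), I = params$I0,
             I_lag1 = 0, I_lag2 = 0, F = 0, F_history = 0)
  class(st) <- "fb_state"
  st
}

#' Juvenile classes targeted by management
#'
#' Returns the indices of the `m` most-populated juvenile age classes --
#' the subset of size `m` maximizing total population. Ties are broken
#' toward the oldest (largest-index) class, since management targets the
#' oldest large cohorts.
#'
#' @param j numeric vector of juvenile populations by age class.
#' @param m number of classes to select, `0 <= m <= length(j)`.
#' @return Integer vector of `m` class indices, sorted increasing.
#' @examples
#' select_classes(c(5, 1, 9, 9), 2)  # -> 3 4
#' @export
select_classes <- function(j, m) {
  K <- length(j)
  if (!is.numeric(m) || length(m) != 1L || is.na(m) || m < 0 || m > K ||
      m != round(m))
    stop(sprintf("invalid parameter 'm': must be an integer in [0, %d]", K),
         call. = FALSE)
  if (m == 0L) return(integer(0))
  ord <- order(j, seq_len(K), decreasing = TRUE)
  sort(ord[seq_len(m)])
}
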