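# Stable integer mixing for replicate seeds: cell coordinates and replicate
# index are folded into [0, 2^31) with a fixed LCG-style hash, so a cell's
# seeds depend only on (seed_base, i1, i2, rep) -- never on execution order
# or policy -- and policies compare under common random numbers.
mix_seed <- function(seed_base, ...) {
  m <- 2147483629 # prime < 2^31; 69069 * m stays exact in doubles
  s <- as.numeric(seed_base) %% m
  for (x in c(...)) s <- (s * 69069 + as.numeric(x) + 1) %% m
  as.integer(s)
}

#' Parameter-plane sweep over the burning rates
#'
#' Runs an ensemble for every combination of juvenile burning rate `alpha1`,
#' adult burning rate `alpha2` and policy, and returns a long-format table
#' of ensemble summaries. Replicate seeds are derived from the cell
#' coordinates and replicate index only, so all policies at a cell share the
#' same noise realizations (common random numbers, reducing the Monte-Carlo
#' variance of policy contrasts) and results are independent of the order
#' cells are evaluated in. Percent changes of `max_I` and `mean_S` relative
#' to the `none` policy at the same cell are filled in when a `none` policy
#' is part of the sweep.
#'
#' @param alpha1_grid,alpha2_grid strictly increasing vectors of burning
#'   rates.
#' @param base_params an [fb_params()] object supplying all other
#'   parameters.
#' @param policies list of [fb_policy()] objects; include `fb_policy("none")`
#'   to obtain percent-change columns.
#' @param n_reps replicates per cell and policy.
#' @param seed_base master seed for the sweep.
#' @param keep_reps if `TRUE`, per-replicate `max_I` values are attached as
#'   `attr(x, "reps")` (long data frame), for paired-contrast standard
#'   errors.
#' @return Data frame of class `fb_sweep`: one row per
#'   `(alpha1, alpha2, policy)` with `max_I_mean`, `max_I_se`, `max_F_mean`,
#'   `max_F_se`, `period_I`, `period_F`, `mean_S`, `pct_change_max_I`,
#'   `pct_change_mean_S` and `ok` (`FALSE` flags a diverged cell).
#' @export
fb_sweep <- function(alpha1_grid, alpha2_grid, base_params = fb_params(),
                     policies = list(fb_policy("none")), n_reps = 100,
                     seed_base = base_params$seed, keep_reps = FALSE) {
  if (length(alpha1_grid) == 0 || length(alpha2_grid) == 0)
    stop("sweep grids must be nonempty", call. = FALSE)
  if (is.unsorted(alpha1_grid, strictly = TRUE) ||
      is.unsorted(alpha2_grid, strictly = TRUE))
    stop("sweep grids must be strictly increasing", call. = FALSE)
  if (n_reps < 1) stop("'n_reps' must be >= 1", call. = FALSE)
  labels <- vapply(policies, policy_label, character(1))
  if (anyDuplicated(labels))
    stop("policies must be distinguishable (duplicate labels)", call. = FALSE)

  rows <- list()
  repr <- list()
  for (i1 in seq_along(alpha1_grid)) {
    for (i2 in seq_along(alpha2_grid)) {
      p <- base_params
      p$alpha1 <- alpha1_grid[i1]
      p$alpha2 <- alpha2_grid[i2]
      validate_params(p)
      seeds <- vapply(seq_len(n_reps),
                      function(r) mix_seed(seed_base, i1, i2, r), integer(1))
      for (ip in seq_along(policies)) {
        pol <- policies[[ip]]
        row <- data.frame(alpha1 = p$alpha1, alpha2 = p$alpha2,
                          policy = labels[ip], max_I_mean = NA_real_,
                          max_I_se = NA_real_, max_F_mean = NA_real_,
                          max_F_se = NA_real_, period_I = NA_real_,
                          period_F = NA_real_, mean_S = NA_real_,
                          pct_change_max_I = NA_real_,
                          pct_change_mean_S = NA_real_, ok = FALSE)
        ens <- tryCatch(
          fb_ensemble(p, pol, seeds = seeds, keep_reps = keep_reps),
          error = function(e) NULL)
        if (!is.null(ens)) {
          row$max_I_mean <- ens$max_I_mean
          row$max_I_se <- ens$max_I_se
          row$max_F_mean <- ens$max_F_mean
          row$max_F_se <- ens$max_F_se
          row$period_I <- ens$period_I
          row$period_F <- ens$period_F
          row$mean_S <- ens$mean_S_mean
          row$ok <- TRUE
          if (keep_reps) {
            rr <- attr(ens, "reps")
            repr[[length(repr) + 1L]] <- data.frame(
              alpha1 = p$alpha1, alpha2 = p$alpha2, policy = labels[ip],
              rep = seq_len(nrow(rr)), seed = rr$seed, max_I = rr$max_I,
              mean_S = rr$mean_S)
          }
        }
        rows[[length(rows) + 1L]] <- row
      }
    }
  }
  out <- do.call(rbind, rows)

  if ("none" %in% out$policy) {
    base <- out[out$policy == "none", c("alpha1", "alpha2", "max_I_mean",
                                        "mean_S")]
    names(base)[3:4] <- c("base_max_I", "base_mean_S")
    out <- merge(out, base, by = c("alpha1", "alpha2"), sort = FALSE)
    pc <- function(v, b) ifelse(is.finite(b) & b > 0, 100 * (v - b) / b,
                                NA_real_)
    out$pct_change_max_I <- pc(out$max_I_mean, out$base_max_I)
    out$pct_change_mean_S <- pc(out$mean_S, out$base_mean_S)
    out$base_max_I <- NULL
    out$base_mean_S <- NULL
  }
  out <- out[order(out$alpha1, out$alpha2, out$policy), ]
  rownames(out) <- NULL
  if (keep_reps) attr(out, "reps") <- do.call(rbind, repr)
  attr(out, "n_reps") <- n_reps
  attr(out, "seed_base") <- seed_base
  class(out) <- c("fb_sweep", "data.frame")
  out
}

#' Percent change between two sweeps
#'
#' Per-cell percentage change `100 * (policy - baseline) / baseline` of the
#' ensemble-mean maximum infestation and mean susceptible population, for
#' two sweep tables on the same `(alpha1, alpha2)` grid. Cells with a
#' non-positive baseline are undefined (`NA`), never infinite.
#'
#' @param result_with_policy,result_baseline single-policy `fb_sweep` tables
#'   (or subsets of one table) on matching grids.
#' @return Data frame with `alpha1`, `alpha2`, `pct_change_max_I`,
#'   `pct_change_mean_S`.
#' @export
percent_change <- function(result_with_policy, result_baseline) {
  key <- c("alpha1", "alpha2")
  a <- result_with_policy[order(result_with_policy$alpha1,
                                result_with_policy$alpha2), ]
  b <- result_baseline[order(result_baseline$alpha1,
                             result_baseline$alpha2), ]
  if (nrow(a) != nrow(b) || !isTRUE(all.equal(a[key], b[key],
                                              check.attributes = FALSE)))
    stop("sweep grids do not match", call. = FALSE)
  pc <- function(v, base) ifelse(is.finite(base) & base > 0,
                                 100 * (v - base) / base, NA_real_)
  data.frame(alpha1 = a$alpha1, alpha2 = a$alpha2,
             pct_change_max_I = pc(a$max_I_mean, b$max_I_mean),
             pct_change_mean_S = pc(a$mean_S, b$mean_S))
}

#' Heatmap of a sweep field
#'
#' @param x an `fb_sweep`.
#' @param field column to map (default `"max_I_mean"`).
#' @param policy which policy's rows to draw.
#' @param ... passed to [graphics::image()].
#' @export
plot.fb_sweep <- function(x, field = "max_I_mean", policy = "none", ...) {
  d <- x[x$policy == policy, ]
  if (nrow(d) == 0) stop("no rows for policy '", policy, "'", call. = FALSE)
  a1 <- sort(unique(d$alpha1))
  a2 <- sort(unique(d$alpha2))
  z <- matrix(NA_real_, length(a1), length(a2))
  z[cbind(match(d$alpha1, a1), match(d$alpha2, a2))] <- d[[field]]
  image(a1, a2, z, col = hcl.colors(64, "viridis"),
        xlab = expression(alpha[1]), ylab = expression(alpha[2]), ...)
  title(sprintf("%s (%s)", field, policy))
  invisible(x)
}
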