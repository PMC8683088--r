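#' Load a run configuration
#'
#' Reads a YAML configuration with optional blocks `params`, `policy`,
#' `sweep` and `output`, plus top-level `seed` and `log_level`. Keys mirror
#' the [fb_params()] and [fb_policy()] argument names; missing keys take the
#' baseline defaults and unknown keys are rejected (typo safety). A
#' top-level `seed` overrides the params seed.
#'
#' @param path path to a YAML file.
#' @return List of class `fb_config` with elements `params` (`fb_params`),
#'   `policy` (`fb_policy`), `sweep` (list or `NULL`), `output` (list),
#'   `seed`, `log_level`.
#' @export
fb_load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  check_keys(cfg, c("params", "policy", "sweep", "output", "seed",
                    "log_level"), "top level")

  pargs <- cfg$params
  if (is.null(pargs)) pargs <- list()
  check_keys(pargs, names(formals(fb_params)), "params")
  params <- do.call(fb_params, pargs)

  polargs <- cfg$policy
  if (is.null(polargs)) polargs <- list()
  check_keys(polargs, names(formals(fb_policy)), "policy")
  policy <- do.call(fb_policy, polargs)

  sweep <- cfg$sweep
  if (!is.null(sweep)) {
    check_keys(sweep, c("alpha1_grid", "alpha2_grid", "n_reps", "seed_base"),
               "sweep")
    if (is.null(sweep$alpha1_grid) || is.null(sweep$alpha2_grid))
      stop("invalid field 'sweep': alpha1_grid and alpha2_grid are required",
           call. = FALSE)
  }

  seed <- if (!is.null(cfg$seed)) as.integer(cfg$seed) else params$seed
  params$seed <- seed
  out <- list(params = params, policy = policy, sweep = sweep,
              output = if (is.null(cfg$output)) list() else cfg$output,
              seed = seed,
              log_level = if (is.null(cfg$log_level)) "INFO" else cfg$log_level)
  class(out) <- "fb_config"
  out
}

check_keys <- function(x, allowed, where) {
  bad <- setdiff(names(x), allowed)
  if (length(bad))
    stop(sprintf("unknown key%s in %s: %s", if (length(bad) > 1) "s" else "",
                 where, paste(bad, collapse = ", ")), call. = FALSE)
  invisible(x)
}

#' Write / read a trajectory as CSV with a JSON sidecar
#'
#' `write_trajectory()` stores the yearly columns `year,J,S,I,F,P` with 17
#' significant digits (so round-trips are exact in double precision) and a
#' `<path>.json` sidecar holding the parameters, policy, seed and package
#' version — enough to regenerate the run. `read_trajectory()` restores the
#' `fb_trajectory` object, re-attaching metadata when the sidecar is
#' present.
#'
#' @param traj an `fb_trajectory`.
#' @param path CSV file path.
#' @return `write_trajectory()` returns `path` invisibly;
#'   `read_trajectory()` returns an `fb_trajectory`.
#' @export
write_trajectory <- function(traj, path) {
  cols <- c("year", "J", "S", "I", "F", "P")
  stopifnot(all(cols %in% names(traj)))
  d <- as.data.frame(traj)[, cols]
  for (c in cols[-1]) d[[c]] <- sprintf("%.17g", d[[c]])
  write.csv(d, path, row.names = FALSE, quote = FALSE)
  p <- attr(traj, "params")
  pol <- attr(traj, "policy")
  side <- list(params = unclass(p), policy = unclass(pol),
               seed = attr(traj, "seed"),
               n_clamped = attr(traj, "n_clamped"),
               package_version = as.character(packageVersion("firebeetle")))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  d <- tryCatch(read.csv(path), error = function(e)
    stop("cannot parse trajectory file: ", conditionMessage(e),
         call. = FALSE))
  cols <- c("year", "J", "S", "I", "F", "P")
  if (!identical(names(d), cols))
    stop(sprintf("trajectory schema mismatch: expected columns %s, found %s",
                 paste(cols, collapse = ","),
                 paste(names(d), collapse = ",")), call. = FALSE)
  if (nrow(d) == 0 || any(!vapply(d, is.numeric, logical(1))))
    stop("trajectory schema mismatch: non-numeric or empty columns",
         call. = FALSE)
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    side <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    p <- side$params
    params <- fb_params(r1 = p$r1, beta1 = p$beta1, d = p$d,
                        alpha1 = p$alpha1, alpha2 = p$alpha2,
                        kappa = p$kappa, T = p$T, K = p$K,
                        sigma_F = p$sigma_F, sigma_I = p$sigma_I,
                        horizon = p$horizon, burn_in = p$burn_in,
                        seed = p$seed, j0_frac = p$j0_frac, I0 = p$I0,
                        strict_noise_balance = p$strict_noise_balance)
    attr(d, "params") <- params
    attr(d, "policy") <- do.call(fb_policy, side$policy)
    attr(d, "seed") <- side$seed
    attr(d, "n_clamped") <- side$n_clamped
  }
  class(d) <- c("fb_trajectory", "data.frame")
  d
}

#' Deterministic reference runs
#'
#' Regenerates the noise-free (`sigma_F = sigma_I = 0`) reference
#' trajectories used as golden fixtures in regression tests:
#' `"fig3_point_det"` at the outbreak operating point
#' `alpha1 = 0.02, alpha2 = 0.0025`; `"dampened_point_det"` at the
#' fire-dampened point `alpha1 = 0.01, alpha2 = 0.006`; and
#' `"beetle_free"`, which starts with no infested trees and stays
#' beetle-free.
#'
#' @param name fixture name.
#' @return List with elements `params` and `trajectory`.
#' @export
make_fixture <- function(name) {
  base <- switch(name,
    fig3_point_det = fb_params(alpha1 = 0.02, alpha2 = 0.0025,
                               sigma_F = 0, sigma_I = 0),
    dampened_point_det = fb_params(alpha1 = 0.01, alpha2 = 0.006,
                                   sigma_F = 0, sigma_I = 0),
    beetle_free = fb_params(alpha1 = 0.02, alpha2 = 0.0025,
                            sigma_F = 0, sigma_I = 0, I0 = 0),
    stop("unknown fixture name: ", name, call. = FALSE))
  list(params = base, trajectory = fb_simulate(base, seed = base$seed))
}
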