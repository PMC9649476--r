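# Attractor readout: long-run per-node % activation over repetitions, with
# stationarity detection by window splitting.

#' Estimate the attractor activation profile
#'
#' Simulates `config$reps` trajectories and reads out, for every node, the
#' percentage of time it is active over the retained window (steps
#' `burn_in .. steps`) across all repetitions — the stochastic analogue of
#' the attractor state set. Stationarity is checked by splitting the window
#' in halves and requiring the largest per-node difference of mean
#' activation between halves to be at most `tol` percentage points; if the
#' check fails the horizon is doubled (up to `max_steps`) and the estimate
#' recomputed. The profile is deterministic given the seed.
#'
#' @param model a [boolean_model()].
#' @param config a [sim_config()]; `config$steps` is the starting horizon.
#' @param perturbations list of [perturbation()] specs.
#' @param polymorphisms list of [polymorphism()] specs.
#' @param seed RNG seed (defaults to `config$seed`).
#' @param burn_in steps discarded before the readout window.
#' @param tol stationarity tolerance in percentage points.
#' @param max_steps horizon cap; a profile still non-stationary at the cap
#'   is returned with `stationary = FALSE` and a warning.
#' @return A `bn_profile`: list with `percent` (named vector, 0-100),
#'   `reps`, `burn_in`, `steps`, `scheme`, `stationary`, `seed`.
#' @examples
#' m <- tlr4_model()
#' prof <- estimate_attractor(m, sim_config(reps = 20, seed = 1))
#' round(prof$percent[c("Thrombosis", "Ang2", "MAC", "Phagocytosis")], 1)
#' @export
estimate_attractor <- function(model, config = sim_config(),
                               perturbations = list(),
                               polymorphisms = list(), seed = config$seed,
                               burn_in = 30L, tol = 2, max_steps = 480L) {
  stopifnot(inherits(config, "sim_config"))
  burn_in <- as.integer(burn_in)
  steps <- max(config$steps, burn_in + 2L)
  stationary <- FALSE
  repeat {
    m <- simulate_mean(model, config, perturbations, polymorphisms,
                       seed = seed, steps = steps)
    win <- m[(burn_in + 1L):(steps + 1L), , drop = FALSE]
    nw <- nrow(win)
    h1 <- colMeans(win[seq_len(nw %/% 2L), , drop = FALSE])
    h2 <- colMeans(win[(nw %/% 2L + 1L):nw, , drop = FALSE])
    if (max(abs(h1 - h2)) * 100 <= tol) { stationary <- TRUE; break }
    if (steps * 2L > max_steps) break
    steps <- steps * 2L
  }
  if (!stationary)
    warning(sprintf("activation profile not stationary within %d steps (tol %g pp)",
                    steps, tol), call. = FALSE)
  structure(
    list(percent = 100 * colMeans(win), reps = config$reps,
         burn_in = burn_in, steps = steps, scheme = config$scheme,
         stationary = stationary, seed = seed),
    class = "bn_profile")
}

#' @export
print.bn_profile <- function(x, ...) {
  cat(sprintf("Activation profile: %d reps, window [%d, %d], scheme %s%s\n",
              x$reps, x$burn_in, x$steps, x$scheme,
              if (x$stationary) "" else " (NOT stationary)"))
  print(round(x$percent, 1))
  invisible(x)
}

#' Mean activation time course
#'
#' Per-step mean activation (in %) over repetitions, without burn-in —
#' the data behind antibiotic-timing trajectory figures.
#'
#' @inheritParams estimate_attractor
#' @return Numeric matrix, `config$steps + 1` rows (step 0 = initial state)
#'   by node, values in `[0, 100]`.
#' @export
activation_timecourse <- function(model, config = sim_config(),
                                  perturbations = list(),
                                  polymorphisms = list(),
                                  seed = config$seed) {
  100 * simulate_mean(model, config, perturbations, polymorphisms,
                      seed = seed)
}

#' Write an activation profile as long CSV
#'
#' @param profile a `bn_profile`.
#' @param path output path.
#' @param condition_id condition label written with every row.
#' @return Invisibly, `path`.
#' @export
write_profile_csv <- function(profile, path, condition_id = "baseline") {
  df <- data.frame(node = names(profile$percent),
                   percent_activation = unname(profile$percent),
                   condition_id = condition_id)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a time course as wide CSV
#'
#' @param tc matrix from [activation_timecourse()].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_timecourse_csv <- function(tc, path) {
  df <- data.frame(step = as.integer(rownames(tc)), tc, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
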