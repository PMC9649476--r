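# Perturbation screens: mono, pairwise and antibiotic-combination
# knock-out/over-expression screens against the endpoint nodes, scored by
# relative activation change and the Perturbation Index.

#' Relative activation change
#'
#' The screen score: `(perturbed - baseline) / baseline` of a node's %
#' activation. Both inputs must lie in `[0, 100]`. Degenerate baselines are
#' handled explicitly: `(0, 0)` gives 0 (no change), while an activation
#' appearing from a zero baseline, `(0, x > 0)`, has no defined ratio and
#' returns `NA` — such conditions are excluded from ratio-based hit calling
#' and reported separately.
#'
#' @param baseline_pct,perturbed_pct numeric vectors in `[0, 100]`.
#' @return Numeric vector of signed relative changes (`NA` for
#'   undefined-increase cases).
#' @examples
#' relative_change(50, 60)   # +0.2
#' relative_change(0, 0)     # 0
#' relative_change(0, 30)    # NA: undefined increase
#' @export
relative_change <- function(baseline_pct, perturbed_pct) {
  if (any(baseline_pct < 0 | baseline_pct > 100 |
          perturbed_pct < 0 | perturbed_pct > 100, na.rm = TRUE))
    stop("percent activations must lie in [0, 100]", call. = FALSE)
  out <- ifelse(baseline_pct > 0, (perturbed_pct - baseline_pct) / baseline_pct,
                ifelse(perturbed_pct == 0, 0, NA_real_))
  as.numeric(out)
}

pi_from_relchange <- function(rel) ifelse(is.na(rel), NA_real_, 1 + rel)

#' Perturbation Index categories
#'
#' @param pi numeric Perturbation Index values (perturbed/baseline).
#' @return Character vector: `"negative"` (PI < 0.8), `"neutral"`
#'   (0.8 <= PI <= 1.25), `"positive"` (PI > 1.25), `"undefined"` for `NA`.
#' @export
pi_category <- function(pi) {
  ifelse(is.na(pi), "undefined",
         ifelse(pi < 0.8, "negative",
                ifelse(pi > 1.25, "positive", "neutral")))
}

#' Per-node Perturbation Index between two activation profiles
#'
#' Compares a perturbed attractor profile against a baseline profile node by
#' node: PI = perturbed / baseline, with the same zero-baseline handling as
#' [relative_change()] (both zero gives PI 1, activation from zero is
#' `NA`/"undefined").
#'
#' @param baseline_profile,perturbed_profile `bn_profile` objects from
#'   [estimate_attractor()], or named percent vectors, over identical node
#'   sets.
#' @return Data frame with columns `node`, `baseline_pct`, `perturbed_pct`,
#'   `pi`, `category`.
#' @export
perturbation_index <- function(baseline_profile, perturbed_profile) {
  b <- if (inherits(baseline_profile, "bn_profile"))
    baseline_profile$percent else baseline_profile
  p <- if (inherits(perturbed_profile, "bn_profile"))
    perturbed_profile$percent else perturbed_profile
  if (!identical(sort(names(b)), sort(names(p))))
    stop("profiles cover different node sets", call. = FALSE)
  p <- p[names(b)]
  rel <- relative_change(unname(b), unname(p))
  pi <- pi_from_relchange(rel)
  data.frame(node = names(b), baseline_pct = unname(b),
             perturbed_pct = unname(p), pi = pi, category = pi_category(pi),
             stringsAsFactors = FALSE, row.names = NULL)
}

# beneficial-direction hit call for one endpoint
call_hit <- function(rel, direction, cutoff) {
  !is.na(rel) & !is.na(direction) &
    ((direction == "decrease" & rel <= -cutoff) |
     (direction == "increase" & rel >= cutoff))
}

# score a list of conditions (each: list(id, perturbations, extra cols))
# against the baseline attractor profile
score_conditions <- function(model, conditions, endpoints, cutoff, config,
                             seed, burn_in = 30L,
                             baseline_profile = NULL) {
  if (is.null(baseline_profile))
    baseline_profile <- estimate_attractor(
      model, config, seed = condition_seed(seed, "baseline"),
      burn_in = burn_in)
  bl <- baseline_profile$percent[endpoints]
  dir <- model$endpoint_direction[endpoints]
  rows <- lapply(conditions, function(cond) {
    cseed <- condition_seed(seed, cond$id)
    prof <- estimate_attractor(model, config,
                               perturbations = cond$perturbations,
                               seed = cseed, burn_in = burn_in)
    pp <- prof$percent[endpoints]
    rel <- relative_change(unname(bl), unname(pp))
    pi <- pi_from_relchange(rel)
    base <- data.frame(condition_id = cond$id, stringsAsFactors = FALSE)
    extra <- cond$extra
    df <- cbind(base, extra[rep(1L, length(endpoints)), , drop = FALSE],
                data.frame(endpoint = endpoints,
                           baseline_pct = unname(bl),
                           perturbed_pct = unname(pp),
                           relative_change = rel, PI = pi,
                           category = pi_category(pi),
                           undefined_increase = is.na(rel) & unname(pp) > 0,
                           hit = call_hit(rel, unname(dir), cutoff),
                           stringsAsFactors = FALSE))
    rownames(df) <- NULL
    df
  })
  do.call(rbind, rows)
}

#' Mono-perturbation treatment-target screen
#'
#' Clamps each screen-set node to 0 (knock-out) or 1 (over-expression) from
#' `t_init` onwards, estimates the attractor profile under the clamp, and
#' scores each endpoint by relative activation change against the
#' unperturbed profile. A condition is a hit for an endpoint when the
#' relative change reaches the efficacy cut-off in that endpoint's
#' beneficial direction (decrease for the organ-damage endpoints Thrombosis
#' and Ang2, increase for the bacterial-clearance endpoints Phagocytosis and
#' MAC). Each condition uses an independent seed derived from the master
#' seed and the condition descriptor, so results are order-invariant.
#'
#' @param model a [boolean_model()].
#' @param screen_set nodes to perturb (default `model$screen_set`).
#' @param modes subset of `c("KO", "OE")`.
#' @param endpoints endpoint nodes scored (default `model$endpoints`).
#' @param cutoff efficacy cut-off on `|relative change|` (default 0.2).
#' @param t_init step at which the clamp starts (default 0, infection
#'   onset).
#' @param config a [sim_config()].
#' @param seed master seed (defaults to `config$seed`).
#' @param burn_in attractor burn-in, see [estimate_attractor()].
#' @return Data frame, one row per condition x endpoint: `condition_id`,
#'   `node`, `mode`, `t_init`, `endpoint`, `baseline_pct`, `perturbed_pct`,
#'   `relative_change`, `PI`, `category`, `undefined_increase`, `hit`.
#' @export
mono_screen <- function(model, screen_set = model$screen_set,
                        modes = c("KO", "OE"),
                        endpoints = model$endpoints, cutoff = 0.2,
                        t_init = 0L, config = sim_config(),
                        seed = config$seed, burn_in = 30L) {
  conditions <- list()
  for (node in screen_set) for (mode in modes) {
    p <- perturbation(node, mode, start = t_init)
    conditions[[length(conditions) + 1L]] <- list(
      id = condition_descriptor(list(p)), perturbations = list(p),
      extra = data.frame(node = node, mode = mode, t_init = t_init,
                         stringsAsFactors = FALSE))
  }
  score_conditions(model, conditions, endpoints, cutoff, config, seed,
                   burn_in = burn_in)
}

#' Hit sets per endpoint of a screen result
#'
#' @param screen data frame from [mono_screen()] and friends.
#' @param hit_col which logical column defines a hit.
#' @return Named list (by endpoint) of condition id character vectors.
#' @export
screen_hits <- function(screen, hit_col = "hit") {
  out <- lapply(split(screen, screen$endpoint),
                function(d) sort(unique(d$condition_id[d[[hit_col]]])))
  out[order(names(out))]
}

#' Pairwise (combination) perturbation screen
#'
#' Evaluates all unordered pairs of distinct screen-set nodes under every
#' KO/OE mode assignment, scored exactly as [mono_screen()]. The
#' `novel_hit` column flags combination strategies proper: pair hits on an
#' endpoint for which neither constituent mono perturbation is itself a hit.
#' Both the raw (`hit`) and filtered (`novel_hit`) calls are returned.
#'
#' @inheritParams mono_screen
#' @param mono optional precomputed [mono_screen()] result (same settings);
#'   computed internally when missing.
#' @return Data frame, one row per pair-condition x endpoint, with `node1`,
#'   `mode1`, `node2`, `mode2` and the scoring columns of [mono_screen()]
#'   plus `novel_hit`.
#' @export
pair_screen <- function(model, screen_set = model$screen_set,
                        modes = c("KO", "OE"),
                        endpoints = model$endpoints, cutoff = 0.2,
                        t_init = 0L, config = sim_config(),
                        seed = config$seed, burn_in = 30L, mono = NULL) {
  if (is.null(mono))
    mono <- mono_screen(model, screen_set, modes, endpoints, cutoff, t_init,
                        config, seed, burn_in)
  mono_hit <- stats::setNames(mono$hit,
                              paste(mono$mode, mono$node, mono$endpoint))
  conditions <- list()
  ns <- length(screen_set)
  for (a in seq_len(ns - 1L)) for (b in (a + 1L):ns) {
    for (m1 in modes) for (m2 in modes) {
      p1 <- perturbation(screen_set[[a]], m1, start = t_init)
      p2 <- perturbation(screen_set[[b]], m2, start = t_init)
      conditions[[length(conditions) + 1L]] <- list(
        id = condition_descriptor(list(p1, p2)),
        perturbations = list(p1, p2),
        extra = data.frame(node1 = p1$node, mode1 = m1, node2 = p2$node,
                           mode2 = m2, t_init = t_init,
                           stringsAsFactors = FALSE))
    }
  }
  res <- score_conditions(model, conditions, endpoints, cutoff, config, seed,
                          burn_in = burn_in)
  m1hit <- mono_hit[paste(res$mode1, res$node1, res$endpoint)]
  m2hit <- mono_hit[paste(res$mode2, res$node2, res$endpoint)]
  m1hit[is.na(m1hit)] <- FALSE
  m2hit[is.na(m2hit)] <- FALSE
  res$novel_hit <- res$hit & !m1hit & !m2hit
  res
}

#' Antibiotic-combination screen
#'
#' Mimics antibiotic treatment as a knock-out clamp on the bacterial node
#' starting at `ab_time`, alone (`condition antibiotic-only`) and combined
#' with each screen-set KO/OE clamp (also starting at `ab_time`). Relative
#' changes and hits are scored against the fully unperturbed profile;
#' `ab_baseline_pct` and `relative_change_vs_ab` additionally compare each
#' combination against the antibiotic-only profile.
#'
#' @inheritParams mono_screen
#' @param ab_time step at which bacteria are cleared.
#' @param bacteria_node name of the bacterial node (default `"Bacteria"`).
#' @return Data frame as [mono_screen()] (antibiotic-only rows have
#'   `node = NA`), plus `ab_time`, `ab_baseline_pct`,
#'   `relative_change_vs_ab`.
#' @export
antibiotic_screen <- function(model, screen_set = model$screen_set,
                              modes = c("KO", "OE"),
                              endpoints = model$endpoints, cutoff = 0.2,
                              ab_time = 0L, config = sim_config(),
                              seed = config$seed, burn_in = 30L,
                              bacteria_node = "Bacteria") {
  ab <- perturbation(bacteria_node, "KO", start = ab_time)
  conditions <- list(list(
    id = condition_descriptor(list(ab)), perturbations = list(ab),
    extra = data.frame(node = NA_character_, mode = NA_character_,
                       t_init = ab_time, ab_time = ab_time,
                       stringsAsFactors = FALSE)))
  for (node in setdiff(screen_set, bacteria_node)) for (mode in modes) {
    p <- perturbation(node, mode, start = ab_time)
    conditions[[length(conditions) + 1L]] <- list(
      id = condition_descriptor(list(ab, p)), perturbations = list(ab, p),
      extra = data.frame(node = node, mode = mode, t_init = ab_time,
                         ab_time = ab_time, stringsAsFactors = FALSE))
  }
  res <- score_conditions(model, conditions, endpoints, cutoff, config, seed,
                          burn_in = burn_in)
  ab_rows <- res[res$condition_id == conditions[[1L]]$id, ]
  ab_pct <- stats::setNames(ab_rows$perturbed_pct, ab_rows$endpoint)
  res$ab_baseline_pct <- unname(ab_pct[res$endpoint])
  res$relative_change_vs_ab <-
    relative_change(res$ab_baseline_pct, res$perturbed_pct)
  res
}

#' Perturbation-timing sweep
#'
#' Re-evaluates a perturbation condition with its clamps started at each
#' step of a grid, reporting the endpoint relative changes against the
#' unperturbed profile. All timings and the baseline share one seed (common
#' random numbers), so a start beyond the simulated horizon reproduces the
#' baseline exactly.
#'
#' @param model a [boolean_model()].
#' @param perturbations list of [perturbation()] specs; their `start` is
#'   replaced by each grid value.
#' @param t_inits grid of start steps (default `c(0, 4, 8, 12, 20)`).
#' @param endpoints endpoint nodes scored.
#' @param config a [sim_config()].
#' @param seed common seed.
#' @param burn_in attractor burn-in.
#' @return Data frame: `t_init`, `endpoint`, `baseline_pct`,
#'   `perturbed_pct`, `relative_change`.
#' @export
timing_sweep <- function(model, perturbations,
                         t_inits = c(0L, 4L, 8L, 12L, 20L),
                         endpoints = model$endpoints,
                         config = sim_config(), seed = config$seed,
                         burn_in = 30L) {
  baseline <- estimate_attractor(model, config, seed = seed,
                                 burn_in = burn_in)
  bl <- baseline$percent[endpoints]
  rows <- lapply(t_inits, function(t0) {
    specs <- lapply(perturbations, function(p)
      perturbation(p$node, p$mode, start = t0, end = p$end))
    prof <- estimate_attractor(model, config, perturbations = specs,
                               seed = seed, burn_in = burn_in)
    pp <- prof$percent[endpoints]
    data.frame(t_init = t0, endpoint = endpoints,
               baseline_pct = unname(bl), perturbed_pct = unname(pp),
               relative_change = relative_change(unname(bl), unname(pp)),
               stringsAsFactors = FALSE, row.names = NULL)
  })
  do.call(rbind, rows)
}

#' Write screen results as CSV
#'
#' @param screen data frame from one of the screens.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_screen_csv <- function(screen, path) {
  utils::write.csv(screen, path, row.names = FALSE)
  invisible(path)
}
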