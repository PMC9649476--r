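# Stochastic asynchronous simulation: R-side configuration, rule
# compilation to the engine bytecode, and the simulate() entry point.

#' Simulation configuration
#'
#' @param steps number of update time steps per repetition (the trajectory
#'   additionally contains the initial state as step 0).
#' @param reps number of stochastic repetitions used for attractor readouts.
#' @param seed base RNG seed; repetition `r` (0-based) uses `seed + r`.
#' @param scheme asynchronous update scheme. `"random_order"` updates every
#'   node once per step in a fresh uniform random order, each update seeing
#'   the freshest within-step values; `"single_node"` updates one uniformly
#'   chosen node per step and carries all others over.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(steps = 60L, reps = 100L, seed = 1L,
                       scheme = c("random_order", "single_node")) {
  scheme <- match.arg(scheme)
  steps <- as.integer(steps); reps <- as.integer(reps)
  stopifnot(steps >= 1L, reps >= 1L)
  structure(list(steps = steps, reps = reps, seed = as.numeric(seed),
                 scheme = scheme), class = "sim_config")
}

#' Perturbation (clamp) specification
#'
#' A knock-out clamps a node to 0, an over-expression clamps it to 1, at
#' every step in `[start, end]` (inclusive); a clamp starting at step 0
#' also overrides the initial state. Clamps dominate both rule evaluation
#' and polymorphisms.
#'
#' @param node node name.
#' @param mode `"KO"` (clamp to 0) or `"OE"` (clamp to 1).
#' @param start first clamped step (default 0, i.e. infection onset).
#' @param end last clamped step (default `Inf`, open-ended).
#' @return A list of class `perturbation_spec`.
#' @export
perturbation <- function(node, mode = c("KO", "OE"), start = 0L, end = Inf) {
  mode <- match.arg(mode)
  stopifnot(is.character(node), length(node) == 1L, start >= 0)
  structure(list(node = node, mode = mode, start = as.numeric(start),
                 end = as.numeric(end)), class = "perturbation_spec")
}

#' Polymorphism (fractional activity) specification
#'
#' Models reduced node responsiveness, e.g. a loss-of-function polymorphism:
#' when the node's update rule is satisfied, the node actually switches on
#' only with probability `activity` (independent draws); when the rule is
#' not satisfied the node is 0 as usual. An activity of 1 bypasses the RNG
#' entirely, so a 100%-activity condition is bit-identical to the unaltered
#' model under the same seed.
#'
#' @param node node name.
#' @param activity fraction in `[0, 1]`.
#' @return A list of class `polymorphism_spec`.
#' @export
polymorphism <- function(node, activity) {
  stopifnot(is.character(node), length(node) == 1L,
            is.numeric(activity), length(activity) == 1L,
            activity >= 0, activity <= 1)
  structure(list(node = node, activity = as.numeric(activity)),
            class = "polymorphism_spec")
}

# ---- rule compilation ------------------------------------------------------

# postfix bytecode triples (op, arg1, arg2); see src/engine.cpp
compile_expr <- function(expr, node_index, delays) {
  out <- integer()
  emit <- function(e) {
    switch(e$op,
      var = out[length(out) + 1:3] <<- c(1L, node_index[[e$name]] - 1L, 0L),
      thr = out[length(out) + 1:3] <<-
        c(2L, node_index[[e$name]] - 1L, as.integer(delays[[e$tag]])),
      not = { emit(e$args[[1L]]); out[length(out) + 1:3] <<- c(3L, 0L, 0L) },
      and = { for (a in e$args) emit(a)
              out[length(out) + 1:3] <<- c(4L, length(e$args), 0L) },
      or  = { for (a in e$args) emit(a)
              out[length(out) + 1:3] <<- c(5L, length(e$args), 0L) })
  }
  emit(expr)
  out
}

compile_model <- function(model) {
  node_index <- stats::setNames(seq_along(model$nodes), model$nodes)
  codes <- lapply(model$nodes, function(n)
    compile_expr(model$rules[[n]], node_index, model$delays))
  lens <- vapply(codes, length, 1L) %/% 3L
  # engine evaluation stack is 128 deep; rule depth is bounded by the
  # number of leaves, so check the compiled size
  if (any(lens > 128L))
    stop("rule too large for the engine evaluation stack", call. = FALSE)
  list(code = unlist(codes), offsets = cumsum(c(0L, lens[-length(lens)])),
       lens = lens, node_index = node_index)
}

prepare_clamps <- function(model, perturbations, node_index) {
  specs <- list()
  seen <- character()
  for (p in perturbations) {
    stopifnot(inherits(p, "perturbation_spec"))
    if (!p$node %in% model$nodes)
      stop(sprintf("perturbation names unknown node '%s'", p$node),
           call. = FALSE)
    key <- paste(p$node, p$mode, p$start, p$end)
    if (key %in% seen) next  # identical clamps are idempotent
    if (p$node %in% vapply(specs, `[[`, "", "node"))
      stop(sprintf("conflicting clamps on node '%s'", p$node), call. = FALSE)
    seen <- c(seen, key)
    specs[[length(specs) + 1L]] <- p
  }
  list(
    node = vapply(specs, function(p) node_index[[p$node]] - 1L, 1L),
    mode = vapply(specs, function(p) if (p$mode == "OE") 1L else 0L, 1L),
    start = vapply(specs, function(p) as.integer(p$start), 1L),
    end = vapply(specs, function(p)
      as.integer(min(p$end, .Machine$integer.max)), 1L))
}

prepare_activity <- function(model, polymorphisms, node_index) {
  act <- rep(1.0, length(model$nodes))
  for (p in polymorphisms) {
    stopifnot(inherits(p, "polymorphism_spec"))
    if (!p$node %in% model$nodes)
      stop(sprintf("polymorphism names unknown node '%s'", p$node),
           call. = FALSE)
    act[node_index[[p$node]]] <- p$activity
  }
  act
}

scheme_code <- function(scheme) if (scheme == "random_order") 0L else 1L

# ---- simulation ------------------------------------------------------------

#' Simulate one stochastic trajectory
#'
#' Runs the asynchronous update scheme for `config$steps` steps from the
#' model's initial state (with step-0 clamps already applied), under
#' optional knock-out/over-expression clamps and fractional-activity
#' polymorphisms. The result is deterministic given
#' (model, config, perturbations, polymorphisms, seed).
#'
#' @param model a [boolean_model()].
#' @param config a [sim_config()].
#' @param perturbations list of [perturbation()] specs.
#' @param polymorphisms list of [polymorphism()] specs.
#' @param seed RNG seed for this trajectory (defaults to `config$seed`).
#' @param record_order also record the within-step node update order
#'   (attribute `"order"`), used for replay checks.
#' @return A `bn_trajectory`: integer matrix of `config$steps + 1` rows
#'   (step 0 = initial state) and one 0/1 column per node.
#' @examples
#' m <- tlr4_model()
#' tr <- simulate_bn(m, sim_config(steps = 20, seed = 7))
#' tr[1:5, c("Infection", "Bacteria", "LPS", "TLR4")]
#' @export
simulate_bn <- function(model, config = sim_config(), perturbations = list(),
                        polymorphisms = list(), seed = config$seed,
                        record_order = FALSE) {
  stopifnot(inherits(model, "boolean_model"), inherits(config, "sim_config"))
  prog <- compile_model(model)
  cl <- prepare_clamps(model, perturbations, prog$node_index)
  act <- prepare_activity(model, polymorphisms, prog$node_index)
  res <- cpp_simulate_one(prog$code, prog$offsets, prog$lens,
                          length(model$nodes), unname(model$initial_state),
                          config$steps, scheme_code(config$scheme),
                          as.numeric(seed),
                          cl$node, cl$mode, cl$start, cl$end, act,
                          record_order)
  traj <- res$trajectory
  dimnames(traj) <- list(0:config$steps, model$nodes)
  attr(traj, "scheme") <- config$scheme
  attr(traj, "seed") <- seed
  if (record_order) attr(traj, "order") <- res$order
  class(traj) <- c("bn_trajectory", class(traj))
  traj
}

# mean state over reps at every step; rows = steps 0..steps
simulate_mean <- function(model, config, perturbations = list(),
                          polymorphisms = list(), seed = config$seed,
                          steps = config$steps) {
  prog <- compile_model(model)
  cl <- prepare_clamps(model, perturbations, prog$node_index)
  act <- prepare_activity(model, polymorphisms, prog$node_index)
  m <- cpp_simulate_mean(prog$code, prog$offsets, prog$lens,
                         length(model$nodes), unname(model$initial_state),
                         as.integer(steps), scheme_code(config$scheme),
                         config$reps, as.numeric(seed),
                         cl$node, cl$mode, cl$start, cl$end, act)
  dimnames(m) <- list(0:steps, model$nodes)
  m
}

#' Write a trajectory as wide CSV
#'
#' @param traj a `bn_trajectory` from [simulate_bn()].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_trajectory_csv <- function(traj, path) {
  df <- data.frame(step = as.integer(rownames(traj)),
                   unclass(traj)[, , drop = FALSE], check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---- deterministic condition seeding --------------------------------------

# stable 31-bit polynomial string hash (exact in double arithmetic)
string_hash31 <- function(x) {
  h <- 0
  for (b in utf8ToInt(x)) h <- (h * 31 + b) %% 2147483647
  h
}

#' Derive a per-condition seed from a master seed
#'
#' Screens evaluate many conditions; each gets an independent seed derived
#' from the master seed plus a stable hash of the condition descriptor, so
#' results do not depend on evaluation order and adding conditions never
#' changes existing ones.
#'
#' @param master_seed integer master seed.
#' @param descriptor character condition descriptor.
#' @return A seed in `[0, 2^31 - 1)`.
#' @export
condition_seed <- function(master_seed, descriptor) {
  (as.numeric(master_seed) + string_hash31(descriptor)) %% 2147483647
}

# canonical descriptor: sorted unique "MODE:node:start" atoms
condition_descriptor <- function(perturbations) {
  if (!length(perturbations)) return("baseline")
  atoms <- vapply(perturbations, function(p)
    sprintf("%s:%s:%g", p$mode, p$node, p$start), "")
  paste(sort(unique(atoms)), collapse = "+")
}
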