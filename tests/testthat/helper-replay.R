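# Pure-R replay of the compiled engine: given a trajectory with its recorded
# update order, recompute every committed row with eval_expr() and the same
# clamp rules. Used to cross-check the C++ scheduler bit for bit
# (deterministic rules only - polymorphism draws cannot be replayed).

clamp_value_at <- function(perturbations, node, t) {
  for (p in perturbations) {
    if (p$node == node && t >= p$start && t <= p$end)
      return(if (p$mode == "OE") 1L else 0L)
  }
  NULL
}

replay_trajectory <- function(model, traj, perturbations = list()) {
  order <- attr(traj, "order")
  scheme <- attr(traj, "scheme")
  steps <- nrow(traj) - 1L
  nodes <- model$nodes
  hist <- matrix(0L, nrow = steps + 1L, ncol = length(nodes),
                 dimnames = list(0:steps, nodes))
  init <- model$initial_state
  for (nd in nodes) {
    cv <- clamp_value_at(perturbations, nd, 0)
    hist[1L, nd] <- if (is.null(cv)) init[[nd]] else cv
  }
  for (t in seq_len(steps)) {
    cur <- hist[t, ]
    upd <- if (scheme == "random_order") order[t, ] + 1L else order[t, 1L] + 1L
    for (i in upd) {
      nd <- nodes[[i]]
      cv <- clamp_value_at(perturbations, nd, t)
      cur[[nd]] <- if (is.null(cv))
        eval_expr(model$rules[[nd]], hist, t, model$delays, snapshot = cur)
      else cv
    }
    for (nd in nodes) {
      cv <- clamp_value_at(perturbations, nd, t)
      if (!is.null(cv)) cur[[nd]] <- cv
    }
    hist[t + 1L, ] <- cur
  }
  hist
}

# long-run engine estimate: window time-average of the mean trajectory
engine_longrun <- function(model, scheme, reps = 10000, steps = 300,
                           burn = 150, seed = 3) {
  cfg <- sim_config(steps = steps, reps = reps, seed = seed, scheme = scheme)
  m <- sepsisBN:::simulate_mean(model, cfg)
  colMeans(m[(burn + 1):(steps + 1), , drop = FALSE])
}
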