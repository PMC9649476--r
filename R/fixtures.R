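# Toy Boolean networks with exactly computable long-run behaviour, used to
# validate the stochastic engine against a full Markov-chain solution.

# small deterministic LCG so fixture generation never touches R's RNG
lcg_new <- function(seed) {
  state <- as.numeric(seed) %% 2147483647
  function(n) {
    # integer in 1..n
    state <<- (state * 48271) %% 2147483647
    as.integer(state %% n) + 1L
  }
}

#' Generate a small toy Boolean network
#'
#' Motifs with documented expected behaviour:
#' \describe{
#'   \item{`chain`}{feed-forward copy chain `N1 = N1; N2 = N1; ...`,
#'     initial state `N1 = 1`; every node ends permanently active.}
#'   \item{`or_redundant`}{two self-sustaining sources and an endpoint
#'     `E = X | Y`, both sources initially active; `E` stays active unless
#'     both sources are knocked out.}
#'   \item{`oscillator`}{single negated node `A = !A`; long-run activation
#'     1/2 under both schemes.}
#'   \item{`xor_like`}{negation loop `A = !B; B = A`, initial `A = 1`;
#'     long-run activation 1/2 for both nodes, reached through genuinely
#'     stochastic trajectories.}
#'   \item{`delayed_chain`}{`A = A; B = THR_A[d]` with delay `delay`
#'     (default 2); `B` fires only after `A` has been active `delay`
#'     consecutive steps.}
#'   \item{`random`}{`n` nodes with reproducible random delay-free rules
#'     (1-3 regulators, random AND/OR, one optionally negated), node 1
#'     initially active.}
#' }
#'
#' @param motif one of `"chain"`, `"or_redundant"`, `"oscillator"`,
#'   `"xor_like"`, `"delayed_chain"`, `"random"`.
#' @param n node count (`chain`, `random`; at most 10).
#' @param seed generator seed (`random` motif).
#' @param delay threshold delay for `delayed_chain`.
#' @return A [boolean_model()].
#' @export
make_toy_network <- function(motif = c("chain", "or_redundant", "oscillator",
                                       "xor_like", "delayed_chain",
                                       "random"),
                             n = 3L, seed = 1L, delay = 2L) {
  motif <- match.arg(motif)
  n <- as.integer(n)
  stopifnot(n >= 1L, n <= 10L)
  lines <- switch(motif,
    chain = {
      nodes <- paste0("N", seq_len(n))
      c(paste(nodes[1L], "=", nodes[1L]),
        if (n > 1L) paste(nodes[-1L], "=", nodes[-n]))
    },
    or_redundant = c("X = X", "Y = Y", "E = X | Y"),
    oscillator = "A = !A",
    xor_like = c("A = !B", "B = A"),
    delayed_chain = c("A = A", sprintf("B = THR_A[d%d]", delay)),
    random = {
      nodes <- paste0("N", seq_len(n))
      draw <- lcg_new(seed)
      vapply(seq_len(n), function(i) {
        k <- min(draw(3L), n)
        regs <- nodes[vapply(seq_len(k), function(j) draw(n), 1L)]
        regs <- unique(regs)
        if (draw(2L) == 1L && length(regs) > 1L)
          regs[1L] <- paste0("!", regs[1L])
        op <- if (draw(2L) == 1L) " & " else " | "
        paste(nodes[i], "=", paste(regs, collapse = op))
      }, "")
    })
  rules <- parse_rules_file(path = NULL, lines = lines)
  nodes <- names(rules)
  init <- switch(motif,
    chain = , random = , delayed_chain = stats::setNames(1L, nodes[1L]),
    or_redundant = c(X = 1L, Y = 1L),
    oscillator = c(A = 1L),
    xor_like = c(A = 1L))
  endpoints <- switch(motif,
    chain = nodes[n],
    or_redundant = "E",
    delayed_chain = "B",
    character())
  dirs <- if (length(endpoints))
    stats::setNames(rep("decrease", length(endpoints)), endpoints)
  boolean_model(
    rules,
    delays = if (motif == "delayed_chain")
      stats::setNames(as.integer(delay), sprintf("d%d", delay)) else c(),
    initial_state = init, endpoints = endpoints, endpoint_direction = dirs,
    screen_set = setdiff(nodes, endpoints),
    name = paste0("toy_", motif))
}

# all permutations of 1..n as a list (n <= 5 in practice)
all_permutations <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in all_permutations(n - 1L)) {
    for (pos in seq_len(n)) {
      out[[length(out) + 1L]] <- append(p, n, after = pos - 1L)
    }
  }
  out
}

#' Exact long-run activation of a small delay-free model
#'
#' Builds the full state-transition probability matrix of the asynchronous
#' update scheme over all `2^n` states and power-iterates the lazy chain
#' `(I + P) / 2` from the initial state to tolerance `1e-10`. The lazy
#' chain shares the original chain's recurrent classes, per-class
#' stationary distributions and absorption probabilities but is aperiodic,
#' so its limit equals the Cesaro (time-average) limit of the original
#' chain — exactly the quantity the engine's window-averaged readout
#' estimates.
#'
#' For `random_order` the one-step map is averaged over all `n!` update
#' permutations (sequential within-step semantics), so the state space is
#' capped at `n <= 5`; `single_node` allows `n <= 10`.
#'
#' @param model a delay-free [boolean_model()].
#' @param scheme `"single_node"` or `"random_order"`.
#' @return Named numeric vector: exact long-run activation (in `[0, 1]`)
#'   per node.
#' @export
exact_stationary <- function(model,
                             scheme = c("single_node", "random_order")) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(model, "boolean_model"))
  for (node in model$nodes)
    if (expr_has_thr(model$rules[[node]]))
      stop("exact_stationary requires a delay-free model", call. = FALSE)
  n <- length(model$nodes)
  cap <- if (scheme == "single_node") 10L else 5L
  if (n > cap)
    stop(sprintf("exact_stationary supports at most %d nodes for scheme '%s'",
                 cap, scheme), call. = FALSE)
  ns <- 2L^n
  # state s (0-based) has node i active iff bit i-1 of s is set
  bits <- function(s) as.integer(bitwAnd(s %/% 2L^(seq_len(n) - 1L), 1L))
  states <- matrix(vapply(0:(ns - 1L), bits, integer(n)),
                   nrow = ns, ncol = n, byrow = TRUE,
                   dimnames = list(NULL, model$nodes))
  pack <- function(v) sum(v * 2L^(seq_len(n) - 1L))

  P <- matrix(0, ns, ns)
  if (scheme == "single_node") {
    for (s in seq_len(ns)) {
      st <- states[s, ]
      for (i in seq_len(n)) {
        new <- st
        new[i] <- eval_expr_state(model$rules[[i]], st)
        P[s, pack(new) + 1L] <- P[s, pack(new) + 1L] + 1 / n
      }
    }
  } else {
    perms <- all_permutations(n)
    w <- 1 / length(perms)
    for (s in seq_len(ns)) {
      st <- states[s, ]
      for (perm in perms) {
        cur <- st
        for (i in perm) cur[i] <- eval_expr_state(model$rules[[i]], cur)
        P[s, pack(cur) + 1L] <- P[s, pack(cur) + 1L] + w
      }
    }
  }

  v <- numeric(ns)
  v[pack(unname(model$initial_state[model$nodes])) + 1L] <- 1
  lazy <- (diag(ns) + P) / 2
  for (it in seq_len(100000L)) {
    v2 <- as.numeric(v %*% lazy)
    if (max(abs(v2 - v)) <= 1e-10) { v <- v2; break }
    v <- v2
  }
  stats::setNames(as.numeric(v %*% states), model$nodes)
}
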