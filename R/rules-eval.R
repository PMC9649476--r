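# Reference (pure-R) evaluator for rule expressions against a trajectory.
# The compiled simulation engine implements the same semantics; this
# evaluator is the readable contract and is used to cross-check the engine.

#' Evaluate a rule expression at a time step
#'
#' Evaluates a Boolean update expression against a committed state history.
#' Plain node references read the state at step `t - 1`, unless `snapshot`
#' supplies fresher within-step values (the asynchronous scheduler passes the
#' partially updated state when nodes are updated sequentially within a
#' step). A threshold term `THR_X[tag]` with delay `d` is 1 iff `X` was
#' active at all committed steps `t - 1, t - 2, ..., t - d`; steps before 0
#' read the initial state (step 0), which encodes the assumption that the
#' pre-infection history equals the initial condition.
#'
#' @param expr a [`bn_expr`][bn_expr].
#' @param history integer matrix of committed states: row `r + 1` is the
#'   state at step `r` (row 1 is the initial state), columns named by node.
#'   Must contain rows for steps `0 .. t - 1`.
#' @param t time step being computed; `t >= 1`.
#' @param delays named integer vector mapping threshold tags to delays
#'   (positive integers).
#' @param snapshot optional named 0/1 vector of freshest node values used for
#'   plain (non-threshold) reads; defaults to the committed row at `t - 1`.
#' @return 0 or 1.
#' @examples
#' h <- rbind(c(Infection = 1, Bacteria = 0), c(Infection = 1, Bacteria = 1))
#' e <- parse_rule("LPS = Bacteria")$expr
#' eval_expr(e, h, t = 2, delays = c())
#' @export
eval_expr <- function(expr, history, t, delays, snapshot = NULL) {
  stopifnot(inherits(expr, "bn_expr"), is.matrix(history))
  if (t < 1L) stop("t must be >= 1", call. = FALSE)
  if (nrow(history) < t)
    stop(sprintf("history must contain steps 0..%d (%d rows), got %d rows",
                 t - 1L, t, nrow(history)), call. = FALSE)
  nodes <- colnames(history)
  if (is.null(snapshot)) snapshot <- history[t, ]
  read_var <- function(name) {
    if (!name %in% names(snapshot))
      stop(sprintf("unknown node '%s' in rule", name), call. = FALSE)
    as.integer(snapshot[[name]])
  }
  read_thr <- function(name, tag) {
    if (!name %in% nodes)
      stop(sprintf("unknown node '%s' in rule", name), call. = FALSE)
    if (!tag %in% names(delays))
      stop(sprintf("unknown threshold tag '%s'", tag), call. = FALSE)
    d <- as.integer(delays[[tag]])
    steps <- t - seq_len(d)           # t-1 .. t-d
    rows <- pmax(steps, 0L) + 1L      # pre-history reads the initial state
    as.integer(all(history[rows, name] == 1L))
  }
  ev <- function(e) {
    switch(e$op,
      var = read_var(e$name),
      thr = read_thr(e$name, e$tag),
      not = 1L - ev(e$args[[1L]]),
      and = { for (a in e$args) if (ev(a) == 0L) return(0L); 1L },
      or  = { for (a in e$args) if (ev(a) == 1L) return(1L); 0L },
      stop("unknown expression op: ", e$op))
  }
  ev(expr)
}

#' Evaluate an expression on a single static state
#'
#' Convenience for delay-free expressions: evaluates against one named 0/1
#' state vector (errors on threshold terms). Used by the exact Markov-chain
#' oracle.
#'
#' @param expr a delay-free [`bn_expr`][bn_expr].
#' @param state named 0/1 vector.
#' @return 0 or 1.
#' @export
eval_expr_state <- function(expr, state) {
  ev <- function(e) {
    switch(e$op,
      var = {
        if (!e$name %in% names(state))
          stop(sprintf("unknown node '%s' in rule", e$name), call. = FALSE)
        as.integer(state[[e$name]])
      },
      thr = stop("threshold terms are not supported in static evaluation",
                 call. = FALSE),
      not = 1L - ev(e$args[[1L]]),
      and = { for (a in e$args) if (ev(a) == 0L) return(0L); 1L },
      or  = { for (a in e$args) if (ev(a) == 1L) return(1L); 0L },
      stop("unknown expression op: ", e$op))
  }
  ev(expr)
}
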