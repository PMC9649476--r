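# Immune-cell sensitivity analysis: sweep each cell node's fractional
# activity (polymorphism) from 0 to 100% and quantify endpoint response.

#' Polymorphism sensitivity sweep over immune-cell nodes
#'
#' For every cell node and activity level, introduces a fractional-activity
#' polymorphism (the node switches on only `level`% of the times its rule
#' is satisfied), estimates the attractor profile, and scores each endpoint
#' by relative change against the unaltered profile. All conditions and the
#' baseline share one seed (common random numbers); since an activity of 1
#' bypasses the RNG, the 100% level reproduces the baseline exactly and its
#' relative change is identically 0.
#'
#' @param model a [boolean_model()].
#' @param cell_nodes nodes to sweep; defaults to the `host_cell` class.
#' @param levels activity levels in percent (default 0 to 100 by 10).
#' @param endpoints endpoint nodes scored (default `model$endpoints`).
#' @param config a [sim_config()].
#' @param seed common seed (defaults to `config$seed`).
#' @param burn_in attractor burn-in, see [estimate_attractor()].
#' @return Data frame (heatmap-ready): `node`, `level`, `endpoint`,
#'   `baseline_pct`, `perturbed_pct`, `relative_change`.
#' @export
polymorphism_sweep <- function(model,
                               cell_nodes =
                                 model$nodes[model$classes == "host_cell"],
                               levels = seq(0L, 100L, by = 10L),
                               endpoints = model$endpoints,
                               config = sim_config(), seed = config$seed,
                               burn_in = 30L) {
  bad <- setdiff(cell_nodes, model$nodes)
  if (length(bad))
    stop(sprintf("unknown node '%s' in cell_nodes", bad[[1L]]), call. = FALSE)
  baseline <- estimate_attractor(model, config, seed = seed,
                                 burn_in = burn_in)
  bl <- baseline$percent[endpoints]
  rows <- list()
  for (node in cell_nodes) for (lv in levels) {
    prof <- estimate_attractor(
      model, config, polymorphisms = list(polymorphism(node, lv / 100)),
      seed = seed, burn_in = burn_in)
    pp <- prof$percent[endpoints]
    rows[[length(rows) + 1L]] <- data.frame(
      node = node, level = lv, endpoint = endpoints,
      baseline_pct = unname(bl), perturbed_pct = unname(pp),
      relative_change = relative_change(unname(bl), unname(pp)),
      stringsAsFactors = FALSE, row.names = NULL)
  }
  do.call(rbind, rows)
}

#' Cell nodes with considerable endpoint effects
#'
#' Reads the full-deactivation end (level 0) of a [polymorphism_sweep()]
#' and reports every (cell node, endpoint) pair whose absolute relative
#' change reaches the cut-off (inclusive), with the effect direction.
#'
#' @param sweep data frame from [polymorphism_sweep()].
#' @param cutoff threshold on `|relative change|` at level 0 (default 0.2,
#'   the screens' efficacy cut-off).
#' @return Data frame sorted by node then endpoint: `node`, `endpoint`,
#'   `relative_change`, `direction` (`"decrease"`/`"increase"`, the endpoint
#'   response to deactivating the cell).
#' @export
identify_cell_effects <- function(sweep, cutoff = 0.2) {
  d <- sweep[sweep$level == 0, , drop = FALSE]
  keep <- !is.na(d$relative_change) & abs(d$relative_change) >= cutoff
  d <- d[keep, , drop = FALSE]
  out <- data.frame(node = d$node, endpoint = d$endpoint,
                    relative_change = d$relative_change,
                    direction = ifelse(d$relative_change < 0, "decrease",
                                       "increase"),
                    stringsAsFactors = FALSE)
  out <- out[order(out$node, out$endpoint), , drop = FALSE]
  rownames(out) <- NULL
  out
}
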