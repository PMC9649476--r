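# Boolean model container: node list, rules, delays, node classification,
# initial state and endpoint metadata, loaded from a rules file plus a
# YAML/JSON sidecar.

#' Construct a Boolean network model
#'
#' Low-level constructor; most users load models with [load_model()] or
#' [tlr4_model()]. Validates referential closure (every node referenced in a
#' rule is declared), threshold-tag coverage, classification coverage and
#' the initial state.
#'
#' @param rules named list of [`bn_expr`][bn_expr] trees, one per node; the
#'   names define the node order.
#' @param delays named integer vector mapping threshold tags to delays
#'   (positive integers in time steps).
#' @param classes named character vector mapping each node to a class label
#'   (e.g. `pathogen`, `host_cell`, `mediator`, `outcome`, `other`). Nodes
#'   left unspecified default to `"other"`.
#' @param initial_state named 0/1 vector; unspecified nodes start at 0.
#' @param endpoints character vector of endpoint node names.
#' @param endpoint_direction named character vector (`"increase"` or
#'   `"decrease"`) giving the beneficial direction per endpoint.
#' @param screen_set character vector of nodes perturbed by the screens.
#' @param name model name used in printing.
#' @return An object of class `boolean_model`.
#' @export
boolean_model <- function(rules, delays = c(), classes = NULL,
                          initial_state = NULL, endpoints = character(),
                          endpoint_direction = NULL,
                          screen_set = character(), name = "boolean_model") {
  stopifnot(is.list(rules), length(rules) >= 1L, !is.null(names(rules)))
  nodes <- names(rules)
  if (anyDuplicated(nodes))
    stop("duplicate rule for node '", nodes[duplicated(nodes)][1L], "'",
         call. = FALSE)
  delays <- if (length(delays)) {
    d <- as.integer(delays)
    names(d) <- names(delays)
    d
  } else integer()
  if (any(delays < 1L))
    stop("threshold delays must be positive integers", call. = FALSE)

  # referential closure and tag coverage
  for (node in nodes) {
    expr <- rules[[node]]
    refs <- expr_regulators(expr)
    bad <- setdiff(refs, nodes)
    if (length(bad))
      stop(sprintf("rule for '%s' references undeclared node '%s'",
                   node, bad[[1L]]), call. = FALSE)
    badtag <- setdiff(expr_tags(expr), names(delays))
    if (length(badtag))
      stop(sprintf("rule for '%s' uses threshold tag '%s' with no delay in the metadata",
                   node, badtag[[1L]]), call. = FALSE)
  }

  cls <- stats::setNames(rep("other", length(nodes)), nodes)
  if (!is.null(classes)) {
    bad <- setdiff(names(classes), nodes)
    if (length(bad))
      stop(sprintf("classification lists unknown node '%s'", bad[[1L]]),
           call. = FALSE)
    cls[names(classes)] <- as.character(classes)
  }

  init <- stats::setNames(integer(length(nodes)), nodes)
  if (!is.null(initial_state)) {
    bad <- setdiff(names(initial_state), nodes)
    if (length(bad))
      stop(sprintf("initial state names unknown node '%s'", bad[[1L]]),
           call. = FALSE)
    init[names(initial_state)] <- as.integer(initial_state)
  }
  if (!all(init %in% c(0L, 1L)))
    stop("initial state must be 0/1", call. = FALSE)

  bad <- setdiff(endpoints, nodes)
  if (length(bad))
    stop(sprintf("endpoint '%s' is not a model node", bad[[1L]]), call. = FALSE)
  bad <- setdiff(screen_set, nodes)
  if (length(bad))
    stop(sprintf("screen set names unknown node '%s'", bad[[1L]]), call. = FALSE)

  dir <- stats::setNames(rep(NA_character_, length(endpoints)), endpoints)
  if (!is.null(endpoint_direction)) {
    bad <- setdiff(names(endpoint_direction), endpoints)
    if (length(bad))
      stop(sprintf("endpoint direction given for non-endpoint '%s'", bad[[1L]]),
           call. = FALSE)
    dir[names(endpoint_direction)] <- as.character(endpoint_direction)
  }

  structure(
    list(nodes = nodes, rules = rules, delays = delays, classes = cls,
         initial_state = init, endpoints = endpoints,
         endpoint_direction = dir, screen_set = screen_set, name = name),
    class = "boolean_model")
}

#' Load a Boolean network model from a rules file and metadata sidecar
#'
#' The rules file holds one `"Node = expression"` line per node in the rule
#' dialect (see [parse_rule()]); the sidecar (YAML or JSON) supplies
#' threshold delays, the node classification, the initial state, the
#' endpoint set and direction of benefit, and the perturbation screen set.
#' Validation failures (undeclared node references, threshold tags without a
#' delay, classification counts that disagree with
#' `expected_class_counts`, duplicate rules) are fatal and name the
#' offending node or reference.
#'
#' @param rules_path path to the rules file.
#' @param metadata_path path to the YAML (or JSON) sidecar.
#' @return A [boolean_model()].
#' @examples
#' model <- tlr4_model()
#' model
#' @export
load_model <- function(rules_path, metadata_path = NULL) {
  rules <- parse_rules_file(rules_path)
  meta <- list()
  if (!is.null(metadata_path)) {
    meta <- if (grepl("\\.json$", metadata_path, ignore.case = TRUE))
      jsonlite::read_json(metadata_path, simplifyVector = TRUE)
    else yaml::yaml.load_file(metadata_path)
  }
  classes <- NULL
  if (!is.null(meta$classes)) {
    classes <- character()
    for (cl in names(meta$classes)) {
      members <- unlist(meta$classes[[cl]])
      classes[members] <- cl
    }
  }
  delays <- unlist(meta$delays)
  init <- unlist(meta$initial_state)
  model <- boolean_model(
    rules = rules,
    delays = if (is.null(delays)) c() else delays,
    classes = classes,
    initial_state = init,
    endpoints = as.character(unlist(meta$endpoints)),
    endpoint_direction = unlist(meta$endpoint_direction),
    screen_set = as.character(unlist(meta$screen_set)),
    name = tools::file_path_sans_ext(basename(rules_path)))
  if (!is.null(meta$expected_class_counts)) {
    want <- unlist(meta$expected_class_counts)
    got <- table(factor(model$classes, levels = names(want)))
    for (cl in names(want)) {
      if (got[[cl]] != want[[cl]])
        stop(sprintf("class '%s' has %d nodes, metadata expects %d",
                     cl, got[[cl]], want[[cl]]), call. = FALSE)
    }
  }
  model
}

#' The shipped TLR4 early-sepsis model
#'
#' Loads the 42-node TLR4-mediated early-sepsis network distributed with
#' the package: Gram-negative infection activates TLR4 through bacterial
#' LPS, driving immune-cell activation, cytokine signalling, complement and
#' coagulation cascades, read out through four clinical surrogate endpoint
#' nodes (Phagocytosis, MAC, Thrombosis, Ang2). The initial state is the
#' onset of infection (`Infection = 1`, all other nodes 0).
#'
#' @return A [boolean_model()] with 42 nodes.
#' @export
tlr4_model <- function() {
  load_model(system.file("extdata", "tlr4_rules.txt", package = "sepsisBN",
                         mustWork = TRUE),
             system.file("extdata", "tlr4_metadata.yaml", package = "sepsisBN",
                         mustWork = TRUE))
}

#' @export
print.boolean_model <- function(x, ...) {
  cat(sprintf("Boolean network model '%s': %d nodes\n", x$name,
              length(x$nodes)))
  tab <- table(x$classes)
  cat("  classes:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      "\n")
  if (length(x$delays))
    cat("  delays: ", paste(sprintf("%s=%d", names(x$delays), x$delays),
                            collapse = ", "), "\n", sep = "")
  if (length(x$endpoints))
    cat("  endpoints:", paste(x$endpoints, collapse = ", "), "\n")
  invisible(x)
}

#' Structural summary of a model
#'
#' Counts nodes, nodes per class, and directed regulator-to-target edges
#' extracted from the rule expressions (plain and threshold references both
#' count; a regulator appearing several times in one rule counts once).
#'
#' @param model a [boolean_model()].
#' @return A list with `node_count`, `class_counts` (named integer vector)
#'   and `edge_count`.
#' @export
network_stats <- function(model) {
  stopifnot(inherits(model, "boolean_model"))
  edges <- 0L
  for (node in model$nodes)
    edges <- edges + length(expr_regulators(model$rules[[node]]))
  list(node_count = length(model$nodes),
       class_counts = c(table(model$classes)),
       edge_count = edges)
}

#' Edge list of a model
#'
#' @param model a [boolean_model()].
#' @return A data frame with columns `regulator` and `target`, one row per
#'   distinct directed edge. Useful for export to graph tools.
#' @export
model_edges <- function(model) {
  stopifnot(inherits(model, "boolean_model"))
  regs <- lapply(model$nodes, function(n) expr_regulators(model$rules[[n]]))
  data.frame(
    regulator = unlist(regs, use.names = FALSE),
    target = rep(model$nodes, lengths(regs)),
    stringsAsFactors = FALSE)
}

# BoolNet identifiers cannot contain '-'
bnet_name <- function(x) gsub("-", "_", x, fixed = TRUE)

bnet_expr <- function(expr, flatten) {
  fmt <- function(e, parent) {
    s <- switch(e$op,
      var = bnet_name(e$name),
      thr = {
        if (!flatten)
          stop("model contains threshold (delay) terms; BoolNet export is delay-free. ",
               "Pass flatten = TRUE to replace THR_X[tag] by X (lossy).",
               call. = FALSE)
        bnet_name(e$name)
      },
      not = paste0("!", fmt(e$args[[1L]], "not")),
      and = paste(vapply(e$args, fmt, "", parent = "and"), collapse = " & "),
      or  = paste(vapply(e$args, fmt, "", parent = "or"), collapse = " | "))
    needs_paren <- switch(e$op,
      or  = parent %in% c("and", "not"),
      and = parent == "not",
      FALSE)
    if (needs_paren) paste0("(", s, ")") else s
  }
  fmt(expr, "top")
}

#' Export a model in BoolNet format
#'
#' Writes the standard BoolNet `"targets, factors"` text format. The format
#' has no delay semantics: models containing threshold terms are refused
#' unless `flatten = TRUE`, which replaces every `THR_X[tag]` by a plain
#' reference to `X` (a documented, lossy simplification). Hyphens in node
#' names are rewritten to underscores, as BoolNet identifiers do not allow
#' them.
#'
#' @param model a [boolean_model()].
#' @param path output file path.
#' @param flatten replace delay terms by plain references (default `FALSE`).
#' @return Invisibly, the lines written.
#' @export
export_bnet <- function(model, path, flatten = FALSE) {
  stopifnot(inherits(model, "boolean_model"))
  body <- vapply(model$nodes, function(n)
    paste0(bnet_name(n), ", ", bnet_expr(model$rules[[n]], flatten)), "")
  lines <- c("targets, factors", unname(body))
  writeLines(lines, path)
  invisible(lines)
}
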