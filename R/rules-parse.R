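# Rule language: Boolean update functions with time-delay threshold terms.
#
# Dialect, one rule per line:
#   Node = expr
# where expr combines identifiers with & (AND), | (OR), ! (NOT), parentheses
# and delay terms THR_<node>[<tag>].  "&!" is ordinary AND followed by unary
# NOT, so "A &! B" parses as A & (!B).  Identifiers may contain letters,
# digits, '-' and '_' (e.g. "TNF-a", "Act-Mon"); display names are kept
# verbatim.  Precedence: NOT > AND > OR, parentheses override.

#' Construct rule-expression AST nodes
#'
#' Internal constructors for the abstract syntax tree of a Boolean update
#' function. `bn_and()`/`bn_or()` flatten nested same-operator children and
#' require at least two operands after flattening; `bn_not()` takes exactly
#' one.
#'
#' @param name node (for `bn_var`) or regulator (for `bn_thr`) name.
#' @param tag threshold tag naming the delay (e.g. `"B_CL"`).
#' @param x,... child expressions.
#' @return An object of class `bn_expr`: a list with an `op` field
#'   (`"var"`, `"thr"`, `"not"`, `"and"`, `"or"`) plus `name`/`tag` or
#'   `args`.
#' @keywords internal
#' @name bn_expr
NULL

new_expr <- function(op, ...) structure(list(op = op, ...), class = "bn_expr")

#' @rdname bn_expr
#' @export
bn_var <- function(name) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  new_expr("var", name = name)
}

#' @rdname bn_expr
#' @export
bn_thr <- function(name, tag) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name),
            is.character(tag), length(tag) == 1L, nzchar(tag))
  new_expr("thr", name = name, tag = tag)
}

#' @rdname bn_expr
#' @export
bn_not <- function(x) {
  stopifnot(inherits(x, "bn_expr"))
  new_expr("not", args = list(x))
}

flatten_nary <- function(op, args) {
  out <- list()
  for (a in args) {
    stopifnot(inherits(a, "bn_expr"))
    if (a$op == op) out <- c(out, a$args) else out <- c(out, list(a))
  }
  out
}

#' @rdname bn_expr
#' @export
bn_and <- function(...) {
  args <- flatten_nary("and", list(...))
  if (length(args) == 1L) return(args[[1L]])
  stopifnot(length(args) >= 2L)
  new_expr("and", args = args)
}

#' @rdname bn_expr
#' @export
bn_or <- function(...) {
  args <- flatten_nary("or", list(...))
  if (length(args) == 1L) return(args[[1L]])
  stopifnot(length(args) >= 2L)
  new_expr("or", args = args)
}

# ---- tokenizer -------------------------------------------------------------

ident_chars <- function(ch) grepl("^[A-Za-z0-9_-]$", ch)

tokenize_expr <- function(text, line = 1L) {
  chars <- strsplit(text, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  toks <- list()
  i <- 1L
  syntax_err <- function(msg, col) {
    stop(sprintf("rule syntax error at line %d, column %d: %s", line, col, msg),
         call. = FALSE)
  }
  while (i <= n) {
    ch <- chars[i]
    if (grepl("^\\s$", ch)) { i <- i + 1L; next }
    if (ch %in% c("&", "|", "!", "(", ")")) {
      toks[[length(toks) + 1L]] <- list(type = ch, col = i)
      i <- i + 1L
      next
    }
    if (ident_chars(ch)) {
      start <- i
      while (i <= n && ident_chars(chars[i])) i <- i + 1L
      word <- paste(chars[start:(i - 1L)], collapse = "")
      # THR_<node>[<tag>] delay term; a bare "THR_x" without brackets is an
      # ordinary identifier
      if (startsWith(word, "THR_") && i <= n && chars[i] == "[") {
        j <- i + 1L
        tstart <- j
        while (j <= n && ident_chars(chars[j])) j <- j + 1L
        if (j > n || chars[j] != "]" || j == tstart)
          syntax_err("malformed threshold term, expected THR_<node>[<tag>]", start)
        tag <- paste(chars[tstart:(j - 1L)], collapse = "")
        node <- substring(word, 5L)
        if (!nzchar(node))
          syntax_err("threshold term is missing a node name", start)
        toks[[length(toks) + 1L]] <-
          list(type = "thr", name = node, tag = tag, col = start)
        i <- j + 1L
      } else {
        toks[[length(toks) + 1L]] <- list(type = "ident", name = word, col = start)
      }
      next
    }
    syntax_err(sprintf("unexpected character '%s'", ch), i)
  }
  toks
}

# ---- recursive-descent parser ---------------------------------------------

parse_tokens <- function(toks, line = 1L, text_len = NA_integer_) {
  pos <- 1L
  syntax_err <- function(msg, col) {
    stop(sprintf("rule syntax error at line %d, column %d: %s", line, col, msg),
         call. = FALSE)
  }
  peek <- function() if (pos <= length(toks)) toks[[pos]] else NULL
  advance <- function() { tok <- toks[[pos]]; pos <<- pos + 1L; tok }
  cur_col <- function() {
    tok <- peek()
    if (is.null(tok)) (if (is.na(text_len)) 0L else text_len + 1L) else tok$col
  }

  parse_primary <- function() {
    tok <- peek()
    if (is.null(tok)) syntax_err("unexpected end of expression", cur_col())
    if (tok$type == "(") {
      advance()
      e <- parse_or()
      tok2 <- peek()
      if (is.null(tok2) || tok2$type != ")")
        syntax_err("expected ')'", cur_col())
      advance()
      return(e)
    }
    if (tok$type == "ident") { advance(); return(bn_var(tok$name)) }
    if (tok$type == "thr") { advance(); return(bn_thr(tok$name, tok$tag)) }
    syntax_err(sprintf("unexpected '%s'", tok$type), tok$col)
  }

  parse_unary <- function() {
    tok <- peek()
    if (!is.null(tok) && tok$type == "!") {
      advance()
      return(bn_not(parse_unary()))
    }
    parse_primary()
  }

  parse_and <- function() {
    args <- list(parse_unary())
    while (!is.null(peek()) && peek()$type == "&") {
      advance()
      args[[length(args) + 1L]] <- parse_unary()
    }
    if (length(args) == 1L) args[[1L]] else do.call(bn_and, args)
  }

  parse_or <- function() {
    args <- list(parse_and())
    while (!is.null(peek()) && peek()$type == "|") {
      advance()
      args[[length(args) + 1L]] <- parse_and()
    }
    if (length(args) == 1L) args[[1L]] else do.call(bn_or, args)
  }

  e <- parse_or()
  if (!is.null(peek()))
    syntax_err(sprintf("unexpected '%s' after end of expression", peek()$type),
               peek()$col)
  e
}

#' Parse one Boolean update rule
#'
#' Parses a single `"Node = expression"` line of the rule dialect into its
#' target node name and expression tree. Parsing is whitespace-insensitive;
#' `"&!"` is read as AND with a negated right operand; operator precedence is
#' NOT > AND > OR with parentheses overriding.
#'
#' @param text one rule line, e.g. `"MAC = THR_C5b[T_MAC]"`.
#' @param line line number used in error messages.
#' @return A list with elements `node` (character) and `expr`
#'   ([`bn_expr`][bn_expr]).
#' @examples
#' r <- parse_rule("Bacteria = Infection &! (Bacteria & THR_MAC[B_CL])")
#' r$node
#' format_expr(r$expr)
#' @export
parse_rule <- function(text, line = 1L) {
  stopifnot(is.character(text), length(text) == 1L)
  eq <- regexpr("=", text, fixed = TRUE)
  if (eq < 0L)
    stop(sprintf("rule syntax error at line %d: missing '='", line), call. = FALSE)
  lhs <- trimws(substring(text, 1L, eq - 1L))
  rhs <- substring(text, eq + 1L)
  if (!grepl("^[A-Za-z0-9_-]+$", lhs))
    stop(sprintf("rule syntax error at line %d: invalid target node name '%s'",
                 line, lhs), call. = FALSE)
  toks <- tokenize_expr(rhs, line = line)
  if (length(toks) == 0L)
    stop(sprintf("rule syntax error at line %d: empty right-hand side", line),
         call. = FALSE)
  # token columns are relative to the right-hand side; offset for messages
  for (k in seq_along(toks)) toks[[k]]$col <- toks[[k]]$col + eq
  expr <- parse_tokens(toks, line = line, text_len = nchar(text))
  list(node = lhs, expr = expr)
}

#' Parse a rules file
#'
#' Reads a plain-text rules file (one `"Node = expression"` line per node,
#' `#` comments and blank lines ignored) into an ordered named list of
#' expression trees.
#'
#' @param path path to the rules file.
#' @param lines alternatively, a character vector of lines (overrides `path`).
#' @return Named list of [`bn_expr`][bn_expr] trees, in file order.
#' @export
parse_rules_file <- function(path, lines = NULL) {
  if (is.null(lines)) lines <- readLines(path, warn = FALSE)
  rules <- list()
  for (k in seq_along(lines)) {
    ln <- sub("#.*$", "", lines[[k]])
    if (!nzchar(trimws(ln))) next
    r <- parse_rule(ln, line = k)
    if (r$node %in% names(rules))
      stop(sprintf("duplicate rule for node '%s' at line %d", r$node, k),
           call. = FALSE)
    rules[[r$node]] <- r$expr
  }
  rules
}

# ---- serialization ---------------------------------------------------------

#' Serialize an expression tree to canonical rule text
#'
#' The canonical form re-parses to an identical tree: OR children are joined
#' with `" | "`, AND children with `" & "` (parenthesising OR operands), and
#' NOT operands are parenthesised unless atomic.
#'
#' @param expr a [`bn_expr`][bn_expr].
#' @return A single character string.
#' @export
format_expr <- function(expr) {
  stopifnot(inherits(expr, "bn_expr"))
  fmt <- function(e, parent) {
    s <- switch(e$op,
      var = e$name,
      thr = sprintf("THR_%s[%s]", e$name, e$tag),
      not = paste0("!", fmt(e$args[[1L]], "not")),
      and = paste(vapply(e$args, fmt, "", parent = "and"), collapse = " & "),
      or  = paste(vapply(e$args, fmt, "", parent = "or"), collapse = " | "),
      stop("unknown expression op: ", e$op))
    needs_paren <- switch(e$op,
      or  = parent %in% c("and", "not"),
      and = parent == "not",
      FALSE)
    if (needs_paren) paste0("(", s, ")") else s
  }
  fmt(expr, parent = "top")
}

#' @rdname format_expr
#' @param node target node name.
#' @export
format_rule <- function(node, expr) paste(node, "=", format_expr(expr))

#' @export
print.bn_expr <- function(x, ...) {
  cat(format_expr(x), "\n")
  invisible(x)
}

# ---- AST queries -----------------------------------------------------------

walk_expr <- function(expr, fn) {
  fn(expr)
  if (!is.null(expr$args)) for (a in expr$args) walk_expr(a, fn)
  invisible(NULL)
}

#' Regulators and threshold tags referenced by an expression
#'
#' @param expr a [`bn_expr`][bn_expr].
#' @return `expr_regulators()`: unique node names read by the expression
#'   (through plain references or threshold terms), in first-appearance
#'   order. `expr_tags()`: unique threshold tag names. `expr_has_thr()`:
#'   logical.
#' @export
expr_regulators <- function(expr) {
  out <- character()
  walk_expr(expr, function(e) {
    if (e$op %in% c("var", "thr")) out[[length(out) + 1L]] <<- e$name
  })
  unique(out)
}

#' @rdname expr_regulators
#' @export
expr_tags <- function(expr) {
  out <- character()
  walk_expr(expr, function(e) {
    if (e$op == "thr") out[[length(out) + 1L]] <<- e$tag
  })
  unique(out)
}

#' @rdname expr_regulators
#' @export
expr_has_thr <- function(expr) length(expr_tags(expr)) > 0L
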