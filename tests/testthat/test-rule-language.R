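# Rule dialect: parsing, canonical serialization, and timed evaluation.

test_that("plain and threshold rules parse to the expected trees", {
  r <- parse_rule("LPS = Bacteria")
  expect_equal(r$node, "LPS")
  expect_equal(r$expr, bn_var("Bacteria"))

  r <- parse_rule("Infection = Infection")  # self-sustaining source node
  expect_equal(r$node, "Infection")
  expect_equal(r$expr, bn_var("Infection"))

  r <- parse_rule("MAC = THR_C5b[T_MAC]")
  expect_equal(r$expr, bn_thr("C5b", "T_MAC"))

  # hyphenated display names survive verbatim, inside and outside THR terms
  r <- parse_rule("TF = THR_Act-Mon[T_TF] | TNF-a")
  expect_equal(r$expr, bn_or(bn_thr("Act-Mon", "T_TF"), bn_var("TNF-a")))
})

test_that("operator precedence is NOT > AND > OR and &! reads as AND NOT", {
  e <- parse_rule("X = A | B & !C")$expr
  expect_equal(e, bn_or(bn_var("A"), bn_and(bn_var("B"), bn_not(bn_var("C")))))
  expect_equal(parse_rule("X = A &! B")$expr,
               parse_rule("X = A & (!B)")$expr)
  # parentheses override, whitespace is irrelevant
  expect_equal(parse_rule("X = (A|B)&C")$expr,
               parse_rule("X = ( A | B ) & C")$expr)
  expect_equal(parse_rule("X = ICAM-1 &TNF-a")$expr,
               bn_and(bn_var("ICAM-1"), bn_var("TNF-a")))
})

test_that("malformed rules fail with positioned syntax errors", {
  expect_error(parse_rule("A = & B"), "syntax error.*column")
  expect_error(parse_rule("A = "), "empty right-hand side")
  expect_error(parse_rule("A B"), "missing '='")
  expect_error(parse_rule("A = (B | C"), "expected '\\)'")
  expect_error(parse_rule("A = THR_X[", ), "malformed threshold")
  expect_error(parse_rule("A = B %% C"), "unexpected character")
  expect_error(
    parse_rules_file(lines = c("A = B", "A = C"), path = NULL),
    "duplicate rule for node 'A'")
})

test_that("canonical serialization round-trips every shipped rule", {
  model <- tlr4_model()
  for (node in model$nodes) {
    txt <- format_rule(node, model$rules[[node]])
    re <- parse_rule(txt)
    expect_identical(re$expr, model$rules[[node]], label = txt)
    # canonical form is a fixed point of format/parse
    expect_identical(format_rule(re$node, re$expr), txt)
  }
})

test_that("timed evaluation honours snapshots and consecutive-step delays", {
  model <- tlr4_model()
  nodes <- model$nodes
  zero <- matrix(0L, nrow = 8, ncol = length(nodes),
                 dimnames = list(0:7, nodes))

  # bacteria appear upon infection while no clearance pathway is active
  h <- zero
  h[, "Infection"] <- 1L
  expect_equal(eval_expr(model$rules[["Bacteria"]], h, t = 3,
                         delays = model$delays), 1L)

  # MAC needs C5b active at the two previous committed steps (delay 2)
  h <- zero
  h[3, "C5b"] <- 1L  # step 2 only
  expect_equal(eval_expr(model$rules[["MAC"]], h, t = 3,
                         delays = model$delays), 0L)
  h[2, "C5b"] <- 1L  # steps 1 and 2
  expect_equal(eval_expr(model$rules[["MAC"]], h, t = 3,
                         delays = model$delays), 1L)

  # delay-1 threshold equals a previous-step read, for random histories
  set.seed(11)
  thr1 <- bn_thr("Act-Neu", "Phag_E")
  var1 <- bn_var("Act-Neu")
  for (k in 1:20) {
    h <- zero
    h[] <- sample(0:1, length(h), replace = TRUE)
    t <- sample(2:7, 1)
    expect_equal(eval_expr(thr1, h, t, model$delays),
                 eval_expr(var1, h, t, model$delays,
                           snapshot = h[t, ]))
  }

  # steps before 0 read the initial state (row 0)
  h <- zero
  h[1, "C5b"] <- 1L  # initial state has C5b on
  expect_equal(eval_expr(bn_thr("C5b", "T_MAC"), h, t = 1, model$delays), 1L)

  # evaluation is pure
  h <- zero; h[, "Infection"] <- 1L
  v <- replicate(5, eval_expr(model$rules[["Bacteria"]], h, 3, model$delays))
  expect_true(all(v == v[1]))
})

test_that("no shipped rule fires from an all-zero history", {
  model <- tlr4_model()
  zero <- matrix(0L, nrow = 6, ncol = length(model$nodes),
                 dimnames = list(0:5, model$nodes))
  for (node in model$nodes)
    expect_equal(eval_expr(model$rules[[node]], zero, t = 4, model$delays),
                 0L, label = node)
})

test_that("evaluation rejects unknown names and invalid steps", {
  model <- tlr4_model()
  h <- matrix(0L, 4, length(model$nodes),
              dimnames = list(0:3, model$nodes))
  expect_error(eval_expr(bn_var("NoSuchNode"), h, 2, model$delays),
               "unknown node")
  expect_error(eval_expr(bn_thr("C5b", "NoSuchTag"), h, 2, model$delays),
               "unknown threshold tag")
  expect_error(eval_expr(bn_var("C5b"), h, 0, model$delays), "t must be")
})
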