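# Screen scoring: relative change, Perturbation Index, mono/pair/antibiotic
# screens and the timing sweep.

test_that("relative change follows the ratio with explicit zero handling", {
  expect_equal(relative_change(50, 60), 0.2)
  expect_equal(relative_change(50, 50), 0)
  expect_equal(relative_change(50, 40), -0.2)
  expect_equal(relative_change(0, 0), 0)
  expect_true(is.na(relative_change(0, 30)))  # undefined increase
  expect_error(relative_change(-1, 50), "\\[0, 100\\]")
  expect_error(relative_change(50, 101), "\\[0, 100\\]")
})

test_that("PI equals 1 + relative change and categorises at 0.8/1.25", {
  b <- c(10, 25, 40, 80, 0, 0)
  p <- c(12, 25, 20, 100, 0, 30)
  rel <- relative_change(b, p)
  pi <- sepsisBN:::pi_from_relchange(rel)
  ok <- !is.na(rel)
  expect_equal(pi[ok], 1 + rel[ok])
  expect_equal(pi_category(c(0.79, 0.8, 1.0, 1.25, 1.26, NA)),
               c("negative", "neutral", "neutral", "neutral", "positive",
                 "undefined"))
})

test_that("perturbation_index compares profiles node by node", {
  b <- c(A = 50, B = 20, C = 0)
  same <- perturbation_index(b, b)
  expect_true(all(same$pi == 1))
  expect_true(all(same$category == "neutral"))

  doubled <- perturbation_index(b, c(A = 100, B = 40, C = 0))
  expect_equal(doubled$pi, c(2, 2, 1))
  expect_equal(doubled$category, c("positive", "positive", "neutral"))

  expect_error(perturbation_index(b, c(A = 1, B = 2, Z = 3)),
               "different node sets")
})

test_that("whole-network PI matrix is mostly neutral for the shipped model", {
  model <- tlr4_model()
  cfg <- sim_config(reps = 30, seed = 7)
  baseline <- estimate_attractor(model, cfg,
                                 seed = condition_seed(7, "baseline"))
  cats <- character()
  suppressWarnings(
    for (node in model$nodes) for (mode in c("KO", "OE")) {
      p <- perturbation(node, mode)
      prof <- estimate_attractor(model, cfg,
                                 perturbations = list(p),
                                 seed = condition_seed(
                                   7, condition_descriptor(list(p))))
      pim <- perturbation_index(baseline, prof)
      cats <- c(cats, pim$category[pim$node != node])
    })
  # single perturbations leave the bulk of the network unchanged
  expect_gt(mean(cats == "neutral"), 0.5)
})

test_that("mono screen finds no hits without a path to the endpoint", {
  rules <- parse_rules_file(lines = c("S = S", "Z = Z", "E = S"),
                            path = NULL)
  toy <- boolean_model(rules, initial_state = c(S = 1L),
                       endpoints = "E",
                       endpoint_direction = c(E = "decrease"),
                       screen_set = "Z")
  res <- mono_screen(toy, config = sim_config(steps = 40, reps = 20,
                                              seed = 2), burn_in = 10)
  expect_false(any(res$hit))
  expect_true(all(res$relative_change == 0))
})

test_that("redundant OR inputs need the double knock-out", {
  toy <- make_toy_network("or_redundant")  # E = X | Y, benefit = decrease
  cfg <- sim_config(steps = 60, reps = 30, seed = 5)
  mono <- mono_screen(toy, screen_set = c("X", "Y"), modes = "KO",
                      config = cfg, burn_in = 20)
  expect_false(any(mono$hit))
  pair <- pair_screen(toy, screen_set = c("X", "Y"), modes = "KO",
                      config = cfg, burn_in = 20, mono = mono)
  ko2 <- pair[pair$endpoint == "E", ]
  expect_true(all(ko2$hit))
  expect_true(all(ko2$novel_hit))
  expect_equal(ko2$relative_change, -1)
})

test_that("duplicate clamps collapse to the mono condition", {
  model <- tlr4_model()
  p <- perturbation("TNF-a", "KO")
  expect_equal(condition_descriptor(list(p, p)),
               condition_descriptor(list(p)))
  cfg <- sim_config(steps = 20, seed = 3)
  expect_identical(
    unclass(simulate_bn(model, cfg, perturbations = list(p, p))),
    unclass(simulate_bn(model, cfg, perturbations = list(p))))
})

test_that("screen results are invariant to condition evaluation order", {
  model <- tlr4_model()
  cfg <- sim_config(reps = 20, seed = 11)
  a <- mono_screen(model, screen_set = c("TNF-a", "IL-10", "C5b"),
                   config = cfg)
  b <- mono_screen(model, screen_set = c("C5b", "TNF-a", "IL-10"),
                   config = cfg)
  a <- a[order(a$condition_id, a$endpoint), ]
  b <- b[order(b$condition_id, b$endpoint), ]
  rownames(a) <- rownames(b) <- NULL
  expect_equal(a, b)
})

test_that("perturbation timing has little effect on mediator screens", {
  model <- tlr4_model()
  tw <- suppressWarnings(timing_sweep(
    model, list(perturbation("IFN-gamma", "KO")), t_inits = c(0, 20),
    config = sim_config(reps = 100, seed = 1)))
  wide <- split(tw$relative_change, tw$t_init)
  expect_equal(wide[["0"]], wide[["20"]], tolerance = 0.1)
})

test_that("a clamp starting beyond the horizon is a no-op", {
  model <- tlr4_model()
  tw <- timing_sweep(model, list(perturbation("TNF-a", "KO")),
                     t_inits = 1000, config = sim_config(reps = 20,
                                                         seed = 2))
  expect_true(all(tw$relative_change == 0))
  expect_equal(tw$perturbed_pct, tw$baseline_pct)
})

test_that("hits persist at a relaxed cut-off under a different seed", {
  model <- tlr4_model()
  sub <- c("TNF-a", "sTNF-R", "C5b", "C3b")
  h1 <- mono_screen(model, screen_set = sub,
                    config = sim_config(reps = 100, seed = 1))
  h2 <- mono_screen(model, screen_set = sub,
                    config = sim_config(reps = 100, seed = 99),
                    cutoff = 0.15)
  for (k in which(h1$hit)) {
    match_row <- h2$condition_id == h1$condition_id[k] &
      h2$endpoint == h1$endpoint[k]
    expect_true(h2$hit[match_row],
                label = paste(h1$condition_id[k], h1$endpoint[k]))
  }
})

test_that("antibiotic screen scores both baselines", {
  model <- tlr4_model()
  res <- suppressWarnings(antibiotic_screen(
    model, screen_set = "sTNF-R", ab_time = 8,
    config = sim_config(reps = 50, seed = 3)))
  ab_only <- res[is.na(res$node), ]
  expect_equal(nrow(ab_only), 4L)  # one row per endpoint
  expect_equal(ab_only$perturbed_pct, ab_only$ab_baseline_pct)
  combo <- res[!is.na(res$node), ]
  expect_true(all(c("relative_change", "relative_change_vs_ab") %in%
                    names(combo)))
  # PI consistency holds wherever the ratio is defined
  ok <- !is.na(res$relative_change)
  expect_equal(res$PI[ok], 1 + res$relative_change[ok])
})
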