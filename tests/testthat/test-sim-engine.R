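# Asynchronous engine: reproducibility, clamps, delays, polymorphisms, and
# a bit-exact pure-R replay of the scheduler.

test_that("identical inputs and seed give bit-identical trajectories", {
  model <- tlr4_model()
  for (scheme in c("random_order", "single_node")) {
    cfg <- sim_config(steps = 40, seed = 9, scheme = scheme)
    t1 <- simulate_bn(model, cfg)
    t2 <- simulate_bn(model, cfg)
    expect_identical(unclass(t1), unclass(t2))
    t3 <- simulate_bn(model, cfg, seed = 10)
    expect_false(identical(unclass(t1), unclass(t3)))
  }
})

test_that("the engine reproduces the pure-R evaluator step by step", {
  model <- tlr4_model()
  for (scheme in c("random_order", "single_node")) {
    cfg <- sim_config(steps = 15, seed = 4, scheme = scheme)
    perts <- list(perturbation("IL-10", "KO", start = 5),
                  perturbation("TNF-a", "OE", start = 0))
    traj <- simulate_bn(model, cfg, perturbations = perts,
                        record_order = TRUE)
    replayed <- replay_trajectory(model, traj, perts)
    expect_identical(replayed, matrix(unclass(traj),
                                      nrow(traj), ncol(traj),
                                      dimnames = dimnames(traj)),
                     label = scheme)
  }
})

test_that("clamps dominate rules, polymorphisms and the initial state", {
  model <- tlr4_model()
  cfg <- sim_config(steps = 30, seed = 2)

  # OE from step 5: held at 1 from there on, untouched before
  traj <- simulate_bn(model, cfg,
                      perturbations = list(perturbation("IL-10", "OE",
                                                        start = 5)))
  expect_true(all(traj[as.character(5:30), "IL-10"] == 1L))

  # bounded clamp releases the node afterwards
  traj <- simulate_bn(model, cfg,
                      perturbations = list(perturbation("Bacteria", "OE",
                                                        start = 0, end = 3)))
  expect_true(all(traj[as.character(0:3), "Bacteria"] == 1L))

  # a clamp starting at step 0 overrides the initial state
  traj <- simulate_bn(model, cfg,
                      perturbations = list(perturbation("Infection", "KO")))
  expect_equal(unname(traj["0", "Infection"]), 0L)
  expect_true(all(traj == 0L))  # nothing can fire without infection

  # clamp beats a zero-activity polymorphism on the same node
  traj <- simulate_bn(model, cfg,
                      perturbations = list(perturbation("TLR4", "OE")),
                      polymorphisms = list(polymorphism("TLR4", 0)))
  expect_true(all(traj[, "TLR4"] == 1L))

  # immediate bacterial clearance: only the infection source stays on
  traj <- simulate_bn(model, cfg,
                      perturbations = list(perturbation("Bacteria", "KO")))
  expect_true(all(traj[, "Infection"] == 1L))
  expect_true(all(traj[, setdiff(model$nodes, "Infection")] == 0L))
})

test_that("conflicting clamps are rejected, identical ones are idempotent", {
  model <- tlr4_model()
  cfg <- sim_config(steps = 10, seed = 1)
  expect_error(
    simulate_bn(model, cfg,
                perturbations = list(perturbation("TLR4", "KO"),
                                     perturbation("TLR4", "OE"))),
    "conflicting clamps")
  expect_error(
    simulate_bn(model, cfg,
                perturbations = list(perturbation("NoSuchNode", "KO"))),
    "unknown node")
  dup <- simulate_bn(model, cfg,
                     perturbations = list(perturbation("TLR4", "KO"),
                                          perturbation("TLR4", "KO")))
  one <- simulate_bn(model, cfg,
                     perturbations = list(perturbation("TLR4", "KO")))
  expect_identical(unclass(dup), unclass(one))
})

test_that("a delay-d node fires only after d consecutive active steps", {
  toy <- make_toy_network("delayed_chain", delay = 2)
  # A starts off and is switched on at step 2 by a clamp; B = THR_A[2]
  toy$initial_state[] <- 0L
  cfg <- sim_config(steps = 8, seed = 1)
  traj <- simulate_bn(toy, cfg,
                      perturbations = list(perturbation("A", "OE",
                                                        start = 2)))
  # first step with A active at both previous committed steps is t = 4
  expect_equal(unname(traj[, "B"]),
               c(0L, 0L, 0L, 0L, 1L, 1L, 1L, 1L, 1L))
})

test_that("polymorphism activity scales long-run activation proportionally", {
  toy <- make_toy_network("chain", n = 3)
  got <- vapply(c(0, 0.3, 0.7, 1), function(p) {
    cfg <- sim_config(steps = 200, reps = 400, seed = 6)
    m <- sepsisBN:::simulate_mean(toy, cfg,
                                  polymorphisms = list(polymorphism("N2", p)))
    mean(m[101:201, "N3"])
  }, 1)
  expect_equal(got, c(0, 0.3, 0.7, 1), tolerance = 0.05)
  expect_true(all(diff(got) >= -0.02))  # monotone in activity
})

test_that("an activity of 1 bypasses the RNG entirely", {
  model <- tlr4_model()
  cfg <- sim_config(steps = 30, seed = 12)
  plain <- simulate_bn(model, cfg)
  poly1 <- simulate_bn(model, cfg,
                       polymorphisms = list(polymorphism("Act-Mon", 1)))
  expect_identical(unclass(plain), unclass(poly1))
})

test_that("frozen regulators make downstream nodes constant", {
  toy <- make_toy_network("chain", n = 4)
  cfg <- sim_config(steps = 50, seed = 3)
  traj <- simulate_bn(toy, cfg,
                      perturbations = list(perturbation("N1", "KO")))
  # source clamped to 0: the feed-forward chain collapses and stays down
  expect_true(all(traj[as.character(10:50), ] == 0L))
})
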