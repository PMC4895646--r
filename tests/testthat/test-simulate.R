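test_that("update_node reproduces hand-computed values", {
  # no parents, no degradation: identity
  expect_equal(update_node(0.5, d = 0), 0.5)
  # one activator, one inhibitor: 0.8*0.5 + 0.6*0.7*0.5 - 0.4*0.3*0.5
  expect_equal(update_node(0.5, d = 0.2, activating = 0.6, inhibiting = 0.3),
               0.55)
  # full degradation plus full inhibition: raw -0.5, clamped to 0
  expect_equal(update_node(0.5, d = 1, inhibiting = 1.0), 0)
  expect_equal(update_node(0.5, d = 1, inhibiting = 1.0, clamp = FALSE), -0.5)
  # parentless node is pure degradation
  expect_equal(update_node(1, d = 0.2), 0.8)
  # input validation
  expect_error(update_node(1.2, d = 0), "\\[0, 1\\]")
  expect_error(update_node(0.5, d = 0.2, activating = 1.5), "\\[0, 1\\]")
  expect_error(update_node(0.5, d = -0.1), "\\[0, 1\\]")
})

test_that("update_node matches the independent oracle on random tuples", {
  set.seed(101)
  for (rep in seq_len(1500)) {
    x <- runif(1)
    d <- runif(1)
    act <- runif(sample(0:4, 1))
    inh <- runif(sample(0:4, 1))
    clamp <- rep %% 2 == 0
    expect_equal(update_node(x, d, act, inh, clamp = clamp),
                 oracle_update(x, d, act, inh, clamp = clamp),
                 tolerance = 1e-12)
  }
})

test_that("step is synchronous and matches per-node updates", {
  net <- signaling_network(
    edges = data.frame(source = "A", target = "B", sign = "+", weight = 1),
    input_nodes = "A")
  cfg <- sim_config(1, degradation = 0)
  out <- step(net, c(1, 0), NULL, 1, cfg)
  expect_equal(unname(out), c(1, 1))  # B reads A's PREVIOUS state

  # two-node mutual inhibition: both must read the old state of the other
  net2 <- signaling_network(
    edges = data.frame(source = c("A", "B"), target = c("B", "A"),
                       sign = "-", weight = 1))
  out2 <- step(net2, c(1, 0), NULL, 1, sim_config(1, degradation = 0))
  expect_equal(unname(out2), c(1, 0))  # A unchallenged, B shut off

  # isolated node decays
  iso <- single_node_network()
  expect_equal(unname(step(iso, 0.5, NULL, 1, sim_config(1, degradation = 0.2))),
               0.4)
  expect_error(step(net, c(1, 0, 0), NULL, 1, cfg), "length")
})

test_that("node order is irrelevant: permuting nodes permutes the output", {
  e <- data.frame(source = c("A", "A", "B"), target = c("B", "C", "C"),
                  sign = c("+", "-", "+"), weight = c(0.7, 0.4, 0.9))
  net1 <- signaling_network(nodes = c("A", "B", "C"), edges = e)
  net2 <- signaling_network(nodes = c("C", "A", "B"), edges = e)
  s <- c(A = 0.9, B = 0.2, C = 0.6)
  cfg <- sim_config(1, degradation = 0.1)
  o1 <- step(net1, s[net1$nodes], NULL, 1, cfg)
  o2 <- step(net2, s[net2$nodes], NULL, 1, cfg)
  expect_equal(o1[net1$nodes], o2[net1$nodes])
})

test_that("simulation trajectories honor shape, determinism and range", {
  net <- toy_network()
  sch <- read_schedule(system.file("extdata", "toy_schedule.csv",
                                   package = "glogsim"))
  cfg <- sim_config(100, degradation = 0.2, seed = 9)
  traj <- simulate_network(net, sch, cfg)
  expect_equal(dim(traj), c(13, 101))
  expect_identical(colnames(traj)[1], "0")
  expect_true(all(traj >= 0 & traj <= 1))
  # bit-identical rerun under the same seed
  expect_identical(unclass(simulate_network(net, sch, cfg)), unclass(traj))
  # different seed changes the initial column
  traj2 <- simulate_network(net, sch, sim_config(100, 0.2, seed = 10))
  expect_false(identical(traj[, 1], traj2[, 1]))
  # schedule may only target input nodes
  bad <- perturbation_schedule(perturbation_event("ERK", 1, start = 1))
  expect_error(simulate_network(net, bad, cfg), "non-input")
  expect_error(sim_config(0), "iterations")
})

test_that("range invariant holds across random networks and schedules", {
  set.seed(5)
  for (s in 1:5) {
    net <- generate_network(network_spec(12, 40, activating_fraction = 0.5,
                                         seed = s, n_inputs = 2))
    sch <- perturbation_schedule(list(
      perturbation_event(net$input_nodes[1], 2 * runif(1) - 1, start = 3),
      perturbation_event(net$input_nodes[2], 2 * runif(1) - 1, start = 7)))
    traj <- simulate_network(net, sch, sim_config(50, runif(1), seed = s))
    expect_true(all(traj >= 0 & traj <= 1))
  }
})

test_that("binary unit-weight zero-degradation dynamics follow the Boolean rule", {
  set.seed(11)
  for (s in 1:8) {
    n <- sample(2:4, 1)
    net <- generate_network(network_spec(
      n, sample.int(n * (n - 1), 1), activating_fraction = 0.6,
      weight_sampler = function(k) rep(1, k), seed = 100 + s))
    states <- expand.grid(rep(list(c(0, 1)), n))
    for (r in seq_len(nrow(states))) {
      x0 <- setNames(as.numeric(states[r, ]), net$nodes)
      got <- step(net, x0, NULL, 1, sim_config(1, degradation = 0))
      expect_identical(got, oracle_boolean_step(net, x0))
    }
  }
})

test_that("a constant activating signal drives the node to A/(A+d)", {
  # closed form for the scalar fixed point x* = A / (A + d)
  for (case in list(c(A = 0.8, d = 0.2), c(A = 0.5, d = 0.3), c(A = 0.2, d = 0.8))) {
    net <- single_node_network()
    sch <- perturbation_schedule(perturbation_event("R", case[["A"]], start = 1))
    traj <- simulate_network(net, sch, sim_config(200, case[["d"]], seed = 1))
    expect_equal(traj[1, "200"], case[["A"]] / (case[["A"]] + case[["d"]]),
                 tolerance = 1e-8)
  }
})

test_that("parentless decay follows the closed geometric form", {
  net <- single_node_network()
  cfg <- sim_config(100, degradation = 0.2, initial = 1.0)
  traj <- simulate_network(net, NULL, cfg)
  expect_equal(unname(traj[1, ]), 0.8 ^ (0:100), tolerance = 1e-15)
  stable <- detect_stable_state(traj, tol = 1e-4, window = 10)
  expect_equal(unname(stable), 0, tolerance = 1e-3)
})

test_that("detect_stable_state distinguishes convergence from oscillation", {
  const <- matrix(0.3, nrow = 2, ncol = 11,
                  dimnames = list(c("a", "b"), 0:10))
  expect_equal(detect_stable_state(const, 1e-6, 5), c(a = 0.3, b = 0.3))
  osc <- matrix(rep(c(0, 1), 6)[1:11], nrow = 1,
                dimnames = list("a", 0:10))
  expect_null(detect_stable_state(osc, 1e-6, 5))
  expect_error(detect_stable_state(const, 1e-6, window = 11), "window")
  expect_error(detect_stable_state(const, tol = 0, window = 5), "tol")
})

test_that("unclamped mode exposes the raw rule leaving [0, 1]", {
  net <- signaling_network(
    edges = data.frame(source = "A", target = "B", sign = "-", weight = 1),
    input_nodes = "A")
  cfg <- sim_config(1, degradation = 1, initial = c(1, 1), clamp = FALSE)
  traj <- simulate_network(net, NULL, cfg)
  expect_lt(traj["B", "1"], 0)
  clamped <- simulate_network(net, NULL,
                              sim_config(1, 1, initial = c(1, 1)))
  expect_equal(clamped["B", "1"], 0)
})

test_that("trajectory CSV output has the documented layouts", {
  net <- chain_network()
  traj <- simulate_network(net, NULL, sim_config(5, 0.2, seed = 1))
  wide <- withr::local_tempfile(fileext = ".csv")
  write_trajectory(traj, wide)
  dfw <- read.csv(wide, check.names = FALSE)
  expect_identical(names(dfw), c("node", as.character(0:5)))
  expect_equal(dfw$node, net$nodes)
  long <- withr::local_tempfile(fileext = ".csv")
  write_trajectory(traj, long, layout = "long")
  dfl <- read.csv(long)
  expect_identical(names(dfl), c("node", "iteration", "activity"))
  expect_equal(nrow(dfl), 3 * 6)
  expect_equal(dfl$activity[dfl$node == "R" & dfl$iteration == 0],
               unname(traj["R", "0"]))
})
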