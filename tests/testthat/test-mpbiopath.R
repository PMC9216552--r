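test_that("equation semantics: AND products, reciprocals, OR averages", {
  cfg <- solver_config()
  # single positive edge copies the input
  sol <- solve_model(build_model(chain_net("+"), c(A = 100), cfg))
  expect_equal(sol$values$x[sol$values$id == "B"], 100)

  # two AND inputs, one inhibitory, both at 10: 10 * (1/10) = 1
  net <- logic_network(data.frame(source = c("A", "B"), target = "C",
                                  polarity = c("+", "-"), logic = "AND"))
  sol <- solve_model(build_model(net, c(A = 10, B = 10), cfg))
  expect_equal(sol$values$x[sol$values$id == "C"], 1)

  # OR over 0.01 and 100 (both activating): arithmetic mean 50.005
  net <- logic_network(data.frame(source = c("A", "B"), target = "C",
                                  polarity = "+", logic = "OR"))
  sol <- solve_model(build_model(net, c(A = 0.01, B = 100), cfg))
  expect_equal(sol$values$x[sol$values$id == "C"], 50.005)

  # geometric_log OR mode averages on the log scale instead
  cfg_geo <- solver_config(or_mode = "geometric_log")
  sol <- solve_model(build_model(net, c(A = 0.01, B = 100), cfg_geo))
  expect_equal(sol$values$x[sol$values$id == "C"], 1)

  # inhibitory chain from a downregulated root clamps at the upper bound
  sol <- solve_model(build_model(chain_net("-"), c(A = 0.01), cfg))
  expect_equal(sol$values$x[sol$values$id == "B"], 100)
})

test_that("model building validates inputs", {
  net <- chain_net("+")
  expect_error(build_model(net, c(Z = 100)), "unknown node")
  expect_error(build_model(net, c(B = 100)), "not root inputs")
  expect_s3_class(build_model(net, c(B = 100), allow_non_root = TRUE),
                  "lp_model")
  expect_error(build_model(net, c(A = 1000)), "outside bounds")
  expect_error(build_model(net, 100), "named")
  expect_error(solver_config(lower_bound = 2), "lower_bound")
  expect_error(solver_config(up_value = 500), "within the bounds")
})

test_that("baseline fixed point: unperturbed networks solve to all ones", {
  for (seed in 1:15) {
    gen <- generate_network(generator_config(seed = seed))
    sol <- solve_model(build_model(gen$network))
    expect_equal(sol$status, "optimal", info = paste("seed", seed))
    expect_equal(sol$values$x, rep(1, nrow(sol$values)),
                 tolerance = 1e-7)
    expect_equal(sol$objective, 0, tolerance = 1e-7)
  }
})

test_that("bound conservation and perturbed-root fixing on arbitrary
           networks", {
  cfg <- solver_config()
  for (seed in 1:15) {
    gen <- generate_network(generator_config(seed = seed,
                                             p_cycle = seed %% 2))
    root <- gen$roles$id[gen$roles$is_root_input][1]
    for (dir in c("up", "down")) {
      sol <- solve_model(build_model(gen$network, setNames(dir, root), cfg))
      expect_true(all(sol$values$x >= cfg$lower_bound - 1e-9 &
                        sol$values$x <= cfg$upper_bound + 1e-9))
      expect_true(all(sol$values$xbar >= cfg$lower_bound - 1e-9 &
                        sol$values$xbar <= cfg$upper_bound + 1e-9))
      want <- if (dir == "up") cfg$up_value else cfg$down_value
      expect_equal(sol$values$x[sol$values$id == root], want)
      expect_gte(sol$objective, 0)
      expect_true(sol$status %in% c("optimal", "feasible"))
    }
  }
})

test_that("solver agrees with the closed-form oracle on pure-AND acyclic
           networks", {
  for (seed in 1:40) {
    gen <- generate_network(generator_config(seed = seed, p_or = 0,
                                             p_cycle = 0))
    roots <- gen$roles$id[gen$roles$is_root_input]
    set.seed(seed)
    pert <- setNames(sample(c(0.01, 0.1, 10, 100), 1), sample(roots, 1))
    sol <- solve_model(build_model(gen$network, pert))
    want <- oracle_topological_eval(gen$network, pert)
    expect_equal(setNames(sol$values$x, sol$values$id), want[sol$values$id],
                 tolerance = 1e-6, info = paste("seed", seed))
  }
})

test_that("reciprocal symmetry: f and 1/f perturbations mirror on pure-AND
           networks", {
  for (seed in 1:10) {
    gen <- generate_network(generator_config(seed = seed, p_or = 0,
                                             p_cycle = 0))
    root <- gen$roles$id[gen$roles$is_root_input][1]
    up <- solve_model(build_model(gen$network, setNames(50, root)))
    dn <- solve_model(build_model(gen$network, setNames(1 / 50, root)))
    expect_equal(up$values$x, 1 / dn$values$x, tolerance = 1e-6,
                 info = paste("seed", seed))
  }
})

test_that("sign of the key-output response matches path parity on single
           paths", {
  for (seed in 1:20) {
    set.seed(seed)
    polarities <- sample(c("+", "-"), sample(1:6, 1), replace = TRUE)
    net <- chain_net(polarities)
    last <- LETTERS[length(polarities) + 1]
    cases <- enumerate_test_cases(net, "A", last)
    act <- predict_activity_cases(net, cases)
    pred <- predict_curator_cases(net, cases)$predicted
    sign_act <- ifelse(act$activity > 1, "up",
                       ifelse(act$activity < 1, "down", "no_change"))
    expect_identical(sign_act, pred, info = paste("seed", seed))
  }
})

test_that("unreachable outputs stay at baseline; feedback yields a
           diagnosed solution", {
  net <- logic_network(data.frame(source = c("A", "C"), target = c("B", "D"),
                                  polarity = "+", logic = "AND"))
  val <- predict_output_activity(net, list(root = "A", direction = "up",
                                           key_output = "D"))
  expect_equal(as.numeric(val), 1)

  # negative feedback loop: root drives B, B and D form an inconsistent
  # loop; solver must return a bounded diagnosed solution, not fail
  loop <- logic_network(data.frame(
    source = c("A", "B", "D", "B"),
    target = c("B", "D", "B", "E"),
    polarity = c("+", "+", "-", "+"),
    logic = "AND"))
  sol <- solve_model(build_model(loop, c(A = "up")))
  expect_true(sol$status %in% c("optimal", "feasible"))
  expect_true(all(sol$values$x >= 0.01 & sol$values$x <= 100))
})
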