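test_that("a single-step circuit behaves like one exponential clock", {
  circ <- single_step_circuit()
  sim <- simulate_circuit(circ, sim_config(tau = 12000,
                                           runs_per_assignment = 5000,
                                           seed = 5))
  for (r in sim$runs) {
    done <- r$status == "FINAL"
    expect_true(all(r$total_steps[done] == 1))
    expect_true(all(r$arrival_time[done] <= 12000))
    # exponential mean 1/k_s ~ 111 s (conditioning on tau is negligible)
    expect_lt(abs(mean(r$arrival_time[done]) - 1 / 0.009), 8)
  }
  te <- transient_estimates(sim)
  expect_lt(abs(te$averaged[["FINAL"]] - (1 - exp(-0.009 * 12000))), 1e-3)
  ex <- exact_transient(circ, c(x = TRUE), 12000)
  expect_equal(ex$FINAL, 1 - exp(-0.009 * 12000), tolerance = 1e-9)
  expect_equal(ex$expected_steps, 1 - exp(-0.009 * 12000), tolerance = 1e-9)
})

test_that("the blocked line circuit matches its closed forms", {
  circ <- line_circuit()
  # blocking always succeeds: only the long INIT->FINAL step remains
  ex <- exact_transient(circ, c(x = FALSE), 12000, block_weight = 1)
  expect_equal(ex$FINAL, 1 - exp(-1.08), tolerance = 1e-9)
  # default 0.7/0.3 blocking: mixture of the long-only chain and the
  # unblocked two-step chain, checked against a dense matrix exponential
  kS <- 0.009; kL <- 0.009 / 100
  Q_blocked <- matrix(c(-kL, kL, 0, 0), 2, 2, byrow = TRUE)
  p_blocked <- as.numeric(Matrix::expm(Q_blocked * 12000)[1, 2])
  # states: INIT, NORM, FINAL; burnt bridges forbid NORM -> INIT
  Q_free <- matrix(c(-(kS + kL), kS, kL,
                     0, -kS, kS,
                     0, 0, 0), 3, 3, byrow = TRUE)
  p_free <- as.numeric(Matrix::expm(Q_free * 12000)[1, 3])
  want <- 0.7 * p_blocked + 0.3 * p_free
  ex2 <- exact_transient(circ, c(x = FALSE), 12000)
  expect_equal(ex2$FINAL, want, tolerance = 1e-8)
  # simulation agrees within Monte Carlo error
  sim <- simulate_circuit(circ, sim_config(runs_per_assignment = 20000,
                                           seed = 9),
                          semantics = "BURNT_BRIDGES")
  pf <- transient_estimates(sim)$per_assignment
  se <- sqrt(want * (1 - want) / 20000)
  expect_lt(abs(pf$FINAL[1] - want), 4 * se)   # assignment x = FALSE
})

test_that("run outcomes are exclusive, exhaustive and internally additive", {
  sim <- simulate_circuit(naive_layout(),
                          sim_config(runs_per_assignment = 2000, seed = 3))
  te <- transient_estimates(sim)
  avg <- te$averaged
  expect_equal(avg[["FINAL"]] + avg[["DEADLOCK"]] + avg[["IN_TRANSIT"]], 1)
  expect_lte(avg[["CORRECT"]], avg[["FINAL"]])
  expect_equal(avg[["CONDITION"]] * avg[["FINAL"]], avg[["CORRECT"]])
  rw <- expected_rewards(sim)
  expect_equal(sum(rw$by_class), rw$total[["mean"]], tolerance = 1e-12)
  for (r in sim$runs)
    expect_equal(rowSums(r$class_steps), r$total_steps)
  # performability mass equals the FINAL probability
  sd_ <- step_distribution(sim, n_max = 200)
  expect_equal(sum(sd_$pmf), avg[["FINAL"]], tolerance = 1e-12)
  expect_true(all(diff(sd_$cdf) >= 0))
  expect_equal(sd_$cdf[nrow(sd_)], avg[["FINAL"]], tolerance = 1e-12)
  # per-class distribution: total mass still the FINAL probability and
  # mean consistent with finishers-only accumulation
  sdc <- step_distribution(sim, reward = "LEAK-SHORT", n_max = 50)
  expect_equal(sum(sdc$pmf), avg[["FINAL"]], tolerance = 1e-12)
  expect_true(all(sdc$pmf >= 0))
})

test_that("deadlock happens at time zero when every route is blocked", {
  circ <- trap_circuit()
  sim <- simulate_circuit(circ, sim_config(runs_per_assignment = 4000,
                                           seed = 21))
  r <- sim$runs[[1]]                 # assignment x = FALSE
  # trapped iff both blocks succeed: 0.7^2
  expect_lt(abs(mean(r$status == "DEAD") - 0.49), 4 * sqrt(0.49 * 0.51 / 4000))
  expect_true(all(r$total_steps[r$status == "DEAD"] == 0))
  ex <- exact_transient(circ, c(x = FALSE), 12000)
  expect_equal(ex$DEADLOCK, 0.49, tolerance = 1e-9)
})

test_that("tau = 0 leaves every walker in transit or dead", {
  sim <- simulate_circuit(line_circuit(),
                          sim_config(tau = 0, runs_per_assignment = 500,
                                     seed = 2))
  te <- transient_estimates(sim)
  expect_equal(te$averaged[["FINAL"]], 0)
})

test_that("identical configuration reproduces identical estimates", {
  cfg <- sim_config(runs_per_assignment = 1000, seed = 77)
  a <- simulate_circuit(toy_circuit(), cfg)
  b <- simulate_circuit(toy_circuit(), cfg)
  expect_identical(transient_estimates(a), transient_estimates(b))
  expect_identical(expected_rewards(a), expected_rewards(b))
})

test_that("unguided semantics keep revisits possible", {
  circ <- line_circuit()
  simu <- simulate_circuit(circ, sim_config(runs_per_assignment = 3000,
                                            seed = 4),
                           semantics = "UNGUIDED")
  # with x = TRUE some runs bounce v1 -> v0 -> v1, taking > 2 steps
  r <- simu$runs[[2]]
  expect_gt(max(r$total_steps), 2)
})
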