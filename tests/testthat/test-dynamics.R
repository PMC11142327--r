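# Numerical semantics: ODE compilation, analytic checks, rateOf, events.

test_that("a first-order decay matches its closed form", {
  tr <- ant_simulate(ant_model(ant_listing(1)), t_end = 10, n_points = 101,
                     seed = 1)
  A <- tr$values[, "A"]
  exact <- 5 * exp(-0.1 * tr$times)
  expect_lt(max(abs(A - exact) / exact), 1e-6)
  expect_lt(max(abs(A + tr$values[, "B"] - 5)), 1e-8)
})

test_that("state dimension reflects boundary marks and rules", {
  sys1 <- ant_compile(ant_model(ant_listing(1)))
  expect_setequal(sys1$state_ids, c("A", "B"))
  sys5 <- ant_compile(ant_model(ant_listing(5)))
  expect_false("A" %in% sys5$state_ids)  # boundary
  expect_false("X" %in% sys5$state_ids)  # forced by assignment
  sys0 <- ant_compile(ant_model("k = 5"))
  expect_length(sys0$state_ids, 0L)
  tr0 <- ant_simulate(sys0, t_end = 1, n_points = 3, seed = 1)
  expect_equal(nrow(tr0$values), 3L)
})

test_that("unit-stoichiometry closed networks conserve total mass", {
  for (seed in 1:4) {
    m <- ant_model(random_chain_model(4, seed))
    tr <- ant_simulate(m, t_end = 20, n_points = 51, seed = 1)
    totals <- rowSums(tr$values[, paste0("S", 1:4)])
    expect_lt(max(abs(totals - totals[1])), 1e-8, label = paste("seed", seed))
  }
})

test_that("forcing functions hold exactly at every output point", {
  tr <- ant_simulate(ant_model(ant_listing(5)), t_end = 10, n_points = 41,
                     seed = 1)
  expect_equal(max(abs(tr$values[, "X"] -
                         (1 + 2.5 * sin(tr$times * 0.5)))), 0)
})

test_that("rateOf evaluates the RHS component for species and rate rules", {
  sys <- ant_compile(ant_model(rateof_model_with_values()))
  # rate rule target: C' = 10*k3 with k3 = 0.25
  expect_equal(ant_rate_of(sys, "C"), 2.5)
  expect_equal(ant_rate_of(sys, "C", state = c(S0 = 99, S1 = 99)), 2.5)
  # species: stoichiometry-weighted sum of reaction rates
  for (seed in 1:5) {
    set.seed(seed)
    st <- c(S0 = runif(1, 0, 5), S1 = runif(1, 0, 5))
    expect_equal(ant_rate_of(sys, "S1", state = st),
                 0.8 * st[["S0"]] - 0.3 * st[["S1"]])
  }
  # species with no reactions or rules has zero rate
  sys2 <- ant_compile(ant_model("A -> B; k*A\nZ = 1\nk = 0.1\nA = 1\nB = 0"))
  expect_equal(ant_rate_of(sys2, "Z"), 0)
})

test_that("rateOf refuses reactions and assignment-rule targets", {
  sys <- ant_compile(ant_model(rateof_model_with_values()))
  expect_error(ant_rate_of(sys, "J0"), class = "ant_restriction_error")
  expect_error(ant_rate_of(sys, "X1"), class = "ant_restriction_error")
})

test_that("assigned observers track rateOf along a trajectory", {
  tr <- ant_simulate(ant_model(rateof_model_with_values()), t_end = 5,
                     n_points = 51, seed = 1)
  # X1 := rateOf(S1) must equal k0*S0 - k1*S1 at every output point
  expect_equal(tr$values[, "X1"],
               0.8 * tr$values[, "S0"] - 0.3 * tr$values[, "S1"],
               tolerance = 1e-9)
  # X2 := rateOf(C) is constant 10*k3
  expect_true(all(abs(tr$values[, "X2"] - 2.5) < 1e-12))
  # central differences of S1 agree with rateOf at interior points (the
  # observed rate passes through zero at the S1 peak, so the error is
  # normalised by the rate's scale rather than pointwise)
  fine <- ant_simulate(ant_model(rateof_model_with_values()), t_end = 5,
                       n_points = 401, seed = 1)
  h <- diff(fine$times)[1]
  n <- length(fine$times)
  fd <- (fine$values[3:n, "S1"] - fine$values[1:(n - 2), "S1"]) / (2 * h)
  err <- abs(fd - fine$values[2:(n - 1), "X1"]) / max(abs(fine$values[, "X1"]))
  expect_lt(max(err), 1e-4)
})

test_that("events fire on a rising edge, draw from the stream, and re-arm", {
  tr <- ant_simulate(ant_model(driven_event_model()), t_end = 5,
                     n_points = 101, seed = 42)
  expect_gte(nrow(tr$events), 1L)
  t_fire <- tr$events$time[1]
  after <- tr$values[tr$times > t_fire, "k0"]
  expect_true(all(after >= 2.5 & after <= 5.5))
  before <- tr$values[tr$times < t_fire, "k0"]
  expect_true(all(before == 2))
  # S1 stays near the threshold from above, so the trigger never returns to
  # false and the event must not re-fire
  expect_equal(nrow(tr$events), 1L)
})

test_that("an event can fire again after its trigger resets", {
  txt <- paste(
    "J0: S0 -> S1; k0*S0",
    "if S1 > 2:",
    "  S1 = 0",
    "S0 = 100; S1 = 0; k0 = 0.05",
    sep = "\n")
  tr <- ant_simulate(ant_model(txt), t_end = 40, n_points = 201, seed = 7)
  expect_gte(nrow(tr$events), 2L)
  expect_true(all(diff(tr$events$time) > 0))
})

test_that("identical seeds give identical trajectories and event logs", {
  a <- ant_simulate(ant_model(driven_event_model()), t_end = 5,
                    n_points = 101, seed = 11)
  b <- ant_simulate(ant_model(driven_event_model()), t_end = 5,
                    n_points = 101, seed = 11)
  expect_identical(a$values, b$values)
  expect_identical(a$events, b$events)
})

test_that("distribution draws initialize state once at time zero", {
  txt <- "S0 = normal(0.5, 0.2)\nS1 = uniform(2.5, 5.5)"
  tr <- ant_simulate(ant_model(txt), t_end = 1, n_points = 5, seed = 3)
  expect_equal(length(unique(tr$values[, "S0"])), 1L)
  expect_true(tr$values[1, "S1"] >= 2.5 && tr$values[1, "S1"] <= 5.5)
})

test_that("initially-true triggers require a falling edge before firing", {
  txt <- paste(
    "k' = 0",
    "if k > 1:",
    "  x = 5",
    "k = 2; x = 0",
    sep = "\n")
  tr <- ant_simulate(ant_model(txt), t_end = 2, n_points = 11, seed = 1)
  expect_equal(nrow(tr$events), 0L)
  expect_true(all(tr$values[, "x"] == 0))
})

test_that("algebraic-rule models are declined by the simulator", {
  expect_error(ant_compile(ant_model(ant_listing(13))),
               class = "ant_not_simulatable")
})
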