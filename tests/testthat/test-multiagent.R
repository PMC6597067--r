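test_that("firing costs follow the degree-normalised form", {
  pars <- agent_params(n = 10, r1 = 1.1, r2 = 5.5)
  # fully connected, silent: cost r1 everywhere
  expect_equal(fire_cost(pars, rep(0, 10)), rep(1.1, 10))
  # all in-neighbours active: r1 + r2 for every node
  q <- rep(1, 10)
  cost <- pars$r1 + pars$r2 * (9 / 9)
  expect_equal(fire_cost(pars, q), rep(cost, 10))
  # isolated node in a sparse graph costs nothing
  adj <- matrix(0, 4, 4)
  adj[1, 2] <- adj[2, 1] <- adj[2, 3] <- 1
  sp <- agent_params(adjacency = adj, r1 = 2, r2 = 3)
  expect_equal(fire_cost(sp, rep(0, 4))[4], 0)
  expect_error(agent_params(adjacency = diag(4)), "self-loops")
})

test_that("the two firing rules are exact complements with the stated limits", {
  pars <- agent_params(n = 5, p = 0.2)
  q0 <- rep(0, 5)
  e <- rep(4, 5)
  s <- 0.2 * sigma_energy(4, 2, 1.5)
  # k = 0, corrected: spontaneous rate p sigma(E)
  expect_equal(fire_probability(pars, q0, e), rep(s, 5), tolerance = 1e-12)
  ap <- agent_params(n = 5, p = 0.2, firing_rule = "as_printed")
  expect_equal(fire_probability(ap, q0, e), rep(1 - s, 5), tolerance = 1e-12)
  # p = 0: corrected never fires, as_printed always "fires"
  z0 <- agent_params(n = 5, p = 0)
  expect_equal(fire_probability(z0, q0, e), rep(0, 5))
  z1 <- agent_params(n = 5, p = 0, firing_rule = "as_printed")
  expect_equal(fire_probability(z1, q0, e), rep(1, 5))
  # corrected probability increases monotonically with active inputs
  pk <- vapply(0:8, function(k) {
    q <- c(rep(1, k), rep(0, 9 - k), 0)
    fire_probability(agent_params(n = 10, p = 0.05), q, rep(4, 10))[10]
  }, numeric(1))
  expect_true(all(diff(pk) > 0))
})

test_that("the compiled simulator reproduces the pure-R reference step for step", {
  pars <- agent_params(n = 40, p = 0.05, eps = 0.01)
  steps <- 60
  tr <- simulate_network(pars, steps = steps, seed = 99, full_history = TRUE)
  # replay with the R reference using the same RNG stream
  set.seed(99)
  e <- runif(40, 0.5 * pars$e_low, pars$e_bar)
  state <- list(q = rep(0L, 40), E = e)
  act <- integer(steps)
  for (t in seq_len(steps)) {
    state <- step_network(state, pars)
    act[t] <- sum(state$q)
  }
  expect_identical(tr$activity[-1], act)
  expect_equal(tr$e_history[steps + 1, ], state$E, tolerance = 1e-12)
})

test_that("energy stays in [0, e_bar] and seeds control reproducibility", {
  pars <- agent_params(n = 625)
  tr <- simulate_network(pars, steps = 2e4, seed = 3)
  expect_gte(tr$e_min, 0)
  expect_lte(tr$e_max, pars$e_bar)
  tr2 <- simulate_network(pars, steps = 2e4, seed = 3)
  expect_identical(tr$activity, tr2$activity)
  tr3 <- simulate_network(pars, steps = 2e4, seed = 4)
  expect_false(identical(tr$activity, tr3$activity))
  # p = 0 with the corrected rule: no node ever fires
  silent <- simulate_network(agent_params(n = 50, p = 0), steps = 500,
                             seed = 1)
  expect_true(all(silent$activity == 0))
})

test_that("avalanche detection applies the zero-bounded definition", {
  av <- detect_avalanches(c(0, 1, 2, 0, 0, 3, 0))
  expect_equal(nrow(av), 2)
  expect_equal(av$duration, c(2L, 1L))
  expect_equal(av$size, c(3, 3))
  expect_equal(nrow(detect_avalanches(rep(0, 10))), 0)
  # boundary-touching runs are discarded
  expect_equal(nrow(detect_avalanches(c(1, 1, 0))), 0)
  expect_equal(nrow(detect_avalanches(c(0, 1, 1))), 0)
  expect_equal(nrow(detect_avalanches(c(1, 0, 2, 0, 1))), 1)
})

test_that("avalanche sizes conserve the activity series and intervals are disjoint", {
  set.seed(5)
  act <- rpois(2000, 0.7)
  av <- detect_avalanches(act)
  for (i in seq_len(nrow(av))) {
    expect_equal(av$size[i], sum(act[av$t_start[i]:av$t_end[i]]))
    expect_gte(av$size[i], av$duration[i])
    expect_equal(act[av$t_start[i] - 1], 0)
    expect_equal(act[av$t_end[i] + 1], 0)
  }
  expect_true(all(diff(av$t_start) > 0))
  expect_true(all(av$t_end[-nrow(av)] < av$t_start[-1]))
})

test_that("exponent estimators recover a known discrete power law", {
  set.seed(8)
  x <- rpowerlaw_discrete(1e5, alpha = 1.5, xmin = 1, xmax = 1e4)
  av <- data.frame(t_start = 1, t_end = 1, duration = x, size = x)
  st <- avalanche_statistics(av, n_bins = 25)
  expect_equal(st$size$exponent, 1.5, tolerance = 0.1 / 1.5)
  expect_equal(st$size$exponent_mle, 1.5, tolerance = 0.1 / 1.5)
  expect_equal(sum(st$size$histogram$count), 1e5)
})

test_that("degenerate or scarce avalanche sets skip fitting but keep histograms", {
  same <- data.frame(t_start = 1, t_end = 1, duration = rep(2L, 60),
                     size = rep(7, 60))
  w <- testthat::capture_warnings(st <- avalanche_statistics(same))
  expect_match(w, "identical", all = TRUE)
  expect_length(w, 2) # one per quantity
  expect_true(is.na(st$size$exponent))
  expect_equal(sum(st$size$histogram$count), 60)
  few <- data.frame(t_start = 1, t_end = 1, duration = 1:10, size = 1:10)
  w2 <- testthat::capture_warnings(st2 <- avalanche_statistics(few))
  expect_match(w2, "skipped", all = TRUE)
  expect_true(is.na(st2$size$exponent))
})

test_that("a sparse user-supplied adjacency drives the compiled path correctly", {
  # directed ring: node i feeds i+1; compare against the R reference
  n <- 12
  adj <- matrix(0, n, n)
  for (i in 1:n) adj[i, i %% n + 1] <- 1
  pars <- agent_params(adjacency = adj, p = 0.3, r1 = 0.2, r2 = 0.2)
  tr <- simulate_network(pars, steps = 80, seed = 17, full_history = TRUE)
  set.seed(17)
  e <- runif(n, 0.5 * pars$e_low, pars$e_bar)
  state <- list(q = rep(0L, n), E = e)
  for (t in 1:80) state <- step_network(state, pars)
  expect_equal(tr$e_history[81, ], state$E, tolerance = 1e-12)
  expect_identical(tr$activity[81], sum(state$q))
})
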