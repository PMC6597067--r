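test_that("sigma_energy matches its closed form, midpoint and limits", {
  expect_equal(sigma_energy(2 / 1.5, e_low = 2, w = 1.5), 0.5)
  expect_equal(sigma_energy(1e6), 1)
  expect_equal(sigma_energy(-1e6), 0)
  # direct numerical evaluation of (tanh(-2) + 1)/2
  expect_equal(sigma_energy(0, e_low = 2, w = 1.5), 0.017986209962091559,
               tolerance = 1e-12)
  # strictly increasing
  e <- seq(-5, 10, by = 0.1)
  expect_true(all(diff(sigma_energy(e, 2, 1.5)) > 0))
})

test_that("the 1-D excitation map has the silent state, direct values and domain checks", {
  expect_equal(step_1d(0, p = 0.1, z = 10), 0)
  expect_equal(step_1d(1, p = 0.1, z = 10), 1 - 0.9^10) # 0.65132156
  expect_error(step_1d(1.2, p = 0.1, z = 10), "\\[0, 1\\]")
  expect_error(step_1d(0.5, p = 1.2, z = 10))
})

test_that("subcritical 1-D orbits decay to zero monotonically; supercritical reach q2* > 1 - e(1-p)^z", {
  set.seed(101)
  for (k in 1:100) {
    p <- runif(1, 0.01, 0.5)
    z <- runif(1, 0.1, 3) * critical_z1(p)
    q <- numeric(300)
    q[1] <- runif(1, 0.05, 1)
    for (t in 2:300) q[t] <- step_1d(q[t - 1], p, z)
    expect_true(all(diff(q) <= 1e-15) || all(diff(q) >= -1e-15),
                info = sprintf("monotone orbit, p=%.3f z=%.2f", p, z))
  }
  # threshold: convergence to 0 iff -z log(1-p) <= 1
  for (p in c(0.01, 0.05, 0.1, 0.2, 0.5)) {
    for (fac in c(0.9, 1.1)) {
      z <- fac * critical_z1(p)
      q <- 0.5
      for (t in 1:5000) q <- step_1d(q, p, z)
      if (fac < 1) {
        expect_lt(q, 1e-8)
      } else {
        expect_gt(q, 1 - exp(1) * (1 - p)^z) # lower bound on q2*
      }
    }
  }
})

test_that("critical connectivities match their closed forms", {
  expect_equal(critical_z1(1 - exp(-1)), 1)
  expect_equal(critical_z1(0.1), 9.4912215810299322, tolerance = 1e-12)
  # small p: z1 ~ 1/p
  expect_equal(critical_z1(1e-4) * 1e-4, 1, tolerance = 1e-4)
  expect_error(critical_z1(1))
  pars <- fig4_params(z = 25)
  # frozen from direct evaluation of the closed forms
  expect_equal(critical_z2(pars), 9.4945793106228233, tolerance = 1e-12)
  expect_equal(critical_z3(pars), 12.125185996861433, tolerance = 1e-12)
  # z2 consistency: -z2 log(1 - p sigma(e_bar)) = 1 exactly
  s <- sigma_energy(pars$e_bar, pars$e_low, pars$w)
  expect_equal(-critical_z2(pars) * log1p(-pars$p * s), 1, tolerance = 1e-14)
  expect_error(critical_z3(mf_params(z = 10, r = 4, e_bar = 4)),
               "not applicable")
})

test_that("step_2d respects the silent point, the unpaid-cost branch and direct evaluation", {
  pars <- mf_params(p = 0.1, z = 210, w = 1.5, e_low = 2, e_bar = 4,
                    eps = 0.05, r = 1)
  s <- step_2d(0, 4, pars)
  expect_equal(s$q, 0)
  expect_equal(s$E, 4)
  # E < r q: no cost paid
  pars10 <- fig4_params(z = 25)
  s2 <- step_2d(0.9, 2, pars10) # r q = 9 > E = 2
  expect_equal(s2$E, (1 - 0.05) * 2 + 0.05 * 4)
  # direct evaluation at q = 1, E = e_bar = 4
  s3 <- step_2d(1, 4, pars)
  sig4 <- (tanh(1.5 * 4 - 2) + 1) / 2 # ~0.99966
  expect_equal(s3$E, 3)
  expect_equal(s3$q, 1 - (1 - 0.1 * sig4)^210, tolerance = 1e-12)
  expect_error(step_2d(0.5, 5, pars), "e_bar")
})

test_that("the energy gate pays the cost at equality (H(0) = 1)", {
  pars <- mf_params(p = 0.1, z = 10, w = 1.5, e_low = 2, e_bar = 4,
                    eps = 0.05, r = 4)
  s <- step_2d(0.5, 2, pars) # E = r q exactly
  expect_equal(s$E, (1 - 0.05) * 2 + 0.05 * 4 - 4 * 0.5)
})

test_that("orbits are deterministic, bounded, and the silent state attracts q0 = 0", {
  pars <- fig4_params(z = 25)
  orb <- simulate_meanfield(pars, q0 = 0, e0 = 1, steps = 200)
  expect_true(all(orb$q == 0))
  # E relaxes to e_bar geometrically at rate 1 - eps
  expect_equal(orb$E, 4 - (4 - 1) * 0.95^(0:200), tolerance = 1e-12)
  o1 <- simulate_meanfield(pars, q0 = 0.37, e0 = 2.2, steps = 500)
  o2 <- simulate_meanfield(pars, q0 = 0.37, e0 = 2.2, steps = 500)
  expect_identical(o1$q, o2$q)
  expect_identical(o1$E, o2$E)
})

test_that("the invariant domain [0,1] x [0, e_bar] is forward-invariant", {
  set.seed(77)
  for (pars in list(fig4_params(z = 25),
                    mf_params(p = 0.3, z = 50, w = 2, e_low = 1,
                              e_bar = 3, eps = 0.2, r = 0.5))) {
    q <- runif(1e6)
    e <- runif(1e6, 0, pars$e_bar)
    s <- step_2d(q, e, pars)
    expect_true(all(s$q >= 0 & s$q <= 1))
    expect_true(all(s$E >= 0 & s$E <= pars$e_bar))
  }
})

test_that("with the sigmoid saturated the activity equation reduces to the 1-D map", {
  # e_low -> -Inf makes sigma identically 1; the unvalidated constructor is
  # used deliberately to probe the limit
  pars <- neurocult:::new_mf_params(p = 0.1, z = 12, w = 1.5, e_low = -1e3,
                                    e_bar = 4, eps = 0.05, r = 1)
  q <- seq(0, 1, by = 0.05)
  s <- step_2d(q, rep(2, length(q)), pars)
  expect_equal(s$q, step_1d(q, p = 0.1 * 1, z = 12), tolerance = 1e-12)
})

test_that("the equilibrium energy curve inverts the activity equation and increases", {
  pars <- fig4_params(z = 50)
  # inverse-function identity: sigma(E*(q)) reproduces the required efficacy
  q <- c(0.005, 0.01, 0.012)
  e <- equilibrium_energy_curve(q, pars)
  lhs <- 1 - (1 - pars$p * sigma_energy(e, pars$e_low, pars$w))^(q * pars$z)
  expect_equal(lhs, q, tolerance = 1e-10)
  # strictly increasing on a feasible stretch
  qs <- seq(0.004, 0.019, length.out = 40)
  expect_true(all(diff(equilibrium_energy_curve(qs, pars)) > 0))
  # at low z a high activity level would require an efficacy beyond sigma's
  # range: no equilibrium there
  expect_error(equilibrium_energy_curve(0.9, fig4_params(10)), "range")
  # the curve crosses the energy balance line E = e_bar - r q / eps once
  line <- pars$e_bar - pars$r * qs / pars$eps
  sgn <- sign(equilibrium_energy_curve(qs, pars) - line)
  expect_equal(sum(diff(sgn) != 0), 1)
})
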