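test_that("erf matches an independent series expansion", {
  xs <- c(0, 0.1, 0.476936, 1, 1.7029, 1.7096, 2.5, 3)
  expect_equal(erf(xs), erf_series(xs), tolerance = 1e-10)
  expect_equal(erf(-xs), -erf_series(xs), tolerance = 1e-10)
  expect_equal(erfinv(erf(c(0.3, 1.2))), c(0.3, 1.2), tolerance = 1e-10)
})

test_that("continuous solution honours its boundary and initial conditions", {
  # x = 0: boundary mass E/p regardless of the other inputs
  expect_equal(continuous_weight(V0 = 70, E = 50 * 9400, p = 9400,
                                 D = 2, x = 0, t = 3), 50)
  # t -> 0+ with x > 0: initial mass
  expect_equal(continuous_weight(V0 = 70, E = 50 * 9400, p = 9400,
                                 D = 1, x = 1, t = 1e-12), 70)
  # t -> infinity at fixed x: boundary mass again
  expect_equal(continuous_weight(V0 = 70, E = 50 * 9400, p = 9400,
                                 D = 1, x = 1, t = 1e12), 50, tolerance = 1e-5)
})

test_that("continuous solution interpolates V0 and E/p at the erf midpoint", {
  # x/(2 sqrt(Dt)) = 0.476936 makes erf = 0.5 to 5 decimals (series oracle)
  u <- 0.476936
  expect_equal(erf_series(u), 0.5, tolerance = 1e-6)
  v <- continuous_weight(V0 = 70, E = 50, p = 1, D = 1, x = 2 * u, t = 1)
  expect_equal(v, 60, tolerance = 1e-5)
})

test_that("continuous solution is a convex combination of V0 and E/p", {
  set.seed(1)
  for (i in 1:50) {
    V0 <- runif(1, 40, 100); Ep <- runif(1, 20, 120)
    v <- continuous_weight(V0 = V0, E = Ep, p = 1, D = runif(1, 0.1, 5),
                           x = runif(1, 0, 3), t = runif(1, 0.01, 10))
    expect_gte(v, min(V0, Ep) - 1e-12)
    expect_lte(v, max(V0, Ep) + 1e-12)
  }
})

test_that("continuous solution rejects non-positive p, D, t", {
  expect_error(continuous_weight(70, 50, p = 0, D = 1, x = 1, t = 1), "positive")
  expect_error(continuous_weight(70, 50, p = 1, D = -1, x = 1, t = 1), "positive")
  expect_error(continuous_weight(70, 50, p = 1, D = 1, x = 1, t = 0), "positive")
  expect_error(continuous_weight(70, 50, p = 1, D = 1, x = -1, t = 1), "non-negative")
})

test_that("one recursion step reproduces limiting cases and the worked week", {
  # beta -> infinity: pure persistence
  expect_equal(weight_step(65.2, -500, alpha = 0.02, beta = 50), 65.2)
  # alpha = 0, beta = 0: both terms vanish
  expect_equal(weight_step(65.2, 1000, alpha = 0, beta = 0), 0)
  # first starvation week from the published constants, against the oracle
  e <- erf_series(1.7096)
  expected <- 69.39 * e + 0.016337 * 7 * (-226.53) * (1 - e)
  expect_equal(weight_step(69.39, -226.53, 0.016337, 1.7096), expected,
               tolerance = 1e-10)
  expect_equal(expected, 67.9017, tolerance = 1e-4)
})

test_that("trajectory modes agree with the hand recursion and with step", {
  # 3-step toy: halving persistence, zero intake
  beta_half <- erfinv(0.5)
  expect_equal(weight_trajectory(c(0, 0, 0), alpha = 3, beta = beta_half,
                                 initial_weight = 10),
               c(5, 2.5, 1.25), tolerance = 1e-6)
  # chained equals the plain-loop oracle on the group data
  gw <- group_weights()
  expect_equal(weight_trajectory(gw$net, 0.016337, 1.7096, gw$w0),
               recursion_oracle(gw$net, 0.016337, 1.7096, gw$w0),
               tolerance = 1e-9)
  # a length-1 simulation is exactly one step
  expect_equal(weight_trajectory(-226.53, 0.016337, 1.7096, 69.39),
               weight_step(69.39, -226.53, 0.016337, 1.7096))
  # one-step-ahead uses observed previous weights
  osa <- weight_trajectory(gw$net, 0.016337, 1.7096, gw$w0,
                           mode = "one_step_ahead", observed = gw$obs)
  prev <- c(gw$w0, gw$obs[-length(gw$obs)])
  expect_equal(osa, weight_step(prev, gw$net, 0.016337, 1.7096))
  expect_error(weight_trajectory(gw$net, 0.016337, 1.7096, gw$w0,
                                 mode = "one_step_ahead"), "observed")
})

test_that("chained trajectories are monotone in intake and affine in start weight", {
  set.seed(2)
  net <- runif(10, -300, 300)
  base <- weight_trajectory(net, 0.016, 1.7, 70)
  for (j in c(1, 5, 10)) {
    bumped <- net; bumped[j] <- bumped[j] + 50
    tr <- weight_trajectory(bumped, 0.016, 1.7, 70)
    expect_true(all(tr[j:10] > base[j:10]))
    expect_equal(tr[seq_len(j - 1)], base[seq_len(j - 1)])
  }
  # doubling the start weight with zero intake doubles everything
  z <- rep(0, 8)
  expect_equal(weight_trajectory(z, 0.02, 1.5, 140),
               2 * weight_trajectory(z, 0.02, 1.5, 70))
})

test_that("constant intake converges geometrically to the fixed point", {
  l <- 1000
  traj <- weight_trajectory(rep(l, 2000), 0.016337, 1.7096, 20)
  ss <- steady_state_weight(0.016337, l)
  expect_equal(ss, 7 * 0.016337 * 1000)
  expect_equal(ss, 114.359, tolerance = 1e-3)
  expect_lt(abs(traj[2000] - ss), 1e-6)
  # contraction rate is erf(beta)
  gaps <- abs(traj - ss)
  expect_equal(gaps[2] / gaps[1], erf(1.7096), tolerance = 1e-6)
  expect_equal(steady_state_weight(0.02, 0), 0)
})

test_that("non-positive trajectories warn but are not clamped", {
  expect_warning(tr <- weight_trajectory(rep(-2000, 50), 0.016, 1.7, 60),
                 "non-positive")
  expect_lt(min(tr), 0)
})

test_that("r_squared definitions behave as documented", {
  obs <- c(3, 5, 4, 6, 8)
  expect_equal(r_squared(obs, obs), 1)
  expect_equal(r_squared(obs, rep(mean(obs), 5)), 0)
  # shift invariance holds only for the squared-correlation variant
  pred <- obs + 0.5
  expect_lt(r_squared(obs, pred), 1)
  expect_equal(r_squared(obs, pred, method = "correlation"), 1)
  expect_lte(r_squared(obs, c(10, -3, 8, 0, 2)), 1)
  expect_error(r_squared(obs, obs[-1]), "equal length")
  expect_error(r_squared(rep(1, 4), rep(1, 4)), "identical")
})

test_that("parameter and series constructors validate their invariants", {
  expect_error(diffusion_params(0.01, -1, 70), "beta")
  expect_error(diffusion_params(0.01, 1.7, 0), "positive")
  expect_error(weight_series(c(1, 1, 2), c(70, 69, 68), net_intake = rep(0, 3)),
               "duplicate")
  expect_error(weight_series(c(2, 1), c(70, 69), net_intake = rep(0, 2)),
               "increasing")
  expect_error(weight_series(1:2, c(-1, 70), net_intake = rep(0, 2)),
               "positive")
})
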