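test_that("reproduction draws Poisson offspring at the modified rate", {
  # 5 groups at beta 2.2 under T = 0.7 reproduce at lambda 1.54 per group;
  # the cell's disperser count is the sum of 5 such draws (mean 7.7)
  n <- 316  # n^2 replicate cells ~ 1e5
  L <- flat_landscape(n, n)
  W <- flat_weather(n, n, tc = 0.7)
  st <- slf_state(2020, matrix(5L, n, n), matrix(0L, n, n), L)
  p <- slf_params(2.2, 1000, 1, 100, 200)
  set.seed(11)
  draws <- reproduce(st, L, W, p, month = 6)
  expect_lt(abs(mean(draws) - 7.70), 0.03)
  expect_gt(var(as.numeric(draws)), 0)  # genuinely stochastic across cells
})

test_that("reproduction is zero out of season, at zero rate, or without groups", {
  L <- flat_landscape(4, 4); W <- flat_weather(4, 4, tc = 0.7)
  Wm <- flat_weather(4, 4, tc = 0.7, mask = c(0L, rep(1L, 11)))
  st <- slf_state(2020, matrix(5L, 4, 4), matrix(0L, 4, 4), L)
  p0 <- slf_params(0, 1000, 1, 100, 200)
  expect_true(all(reproduce(st, L, W, p0, 6) == 0))
  expect_true(all(reproduce(st, L, Wm, slf_params(2, 1000, 1, 1, 2), 1) == 0))
  st0 <- slf_state(2020, matrix(0L, 4, 4), matrix(0L, 4, 4), L)
  expect_true(all(reproduce(st0, L, W, slf_params(2, 1000, 1, 1, 2), 6) == 0))
})

test_that("establishment is Bernoulli((S/N) * T) with host depletion", {
  L <- flat_landscape(1, 1, hosts = 10)
  W <- flat_weather(1, 1, tc = 0.8)
  # S/N = 0.5 via 5 of 10 hosts already infested
  st <- slf_state(2020, matrix(1L, 1, 1), matrix(5L, 1, 1), L)
  set.seed(12)
  hits <- vapply(1:20000, function(i)
    establish(c(1, 1), L, st, W, 6)$established, TRUE)
  expect_lt(abs(mean(hits) - 0.4), 0.01)
  # a success moves one host from susceptible to infested
  set.seed(13)
  repeat {
    r <- establish(c(1, 1), L, st, W, 6)
    if (r$established) break
  }
  expect_equal(r$state$infested_hosts[1, 1], 6L)
  expect_equal(r$state$groups[1, 1], 2L)
  # no hosts, no establishment; full house with T = 1 always establishes
  L0 <- flat_landscape(1, 1, hosts = 0)
  st0 <- slf_state(2020, matrix(0L, 1, 1), matrix(0L, 1, 1), L0)
  expect_false(any(vapply(1:200, function(i)
    establish(c(1, 1), L0, st0, flat_weather(1, 1, 1), 6)$established, TRUE)))
  st1 <- slf_state(2020, matrix(0L, 1, 1), matrix(0L, 1, 1), L)
  expect_true(all(vapply(1:200, function(i)
    establish(c(1, 1), L, st1, flat_weather(1, 1, 1), 6)$established, TRUE)))
})

test_that("a zero reproductive rate freezes the infestation", {
  L <- flat_landscape(6, 6)
  W <- flat_weather(6, 6)
  init <- initial_state(L, c(3, 3), 2020, groups = 4)
  run <- simulate_spread(init, L, W, slf_params(0, 1000, 1, 100, 200),
                         NULL, slf_sim_config(2024, 12))
  for (y in run$years)
    expect_equal(run$states[[as.character(y)]]$infested_hosts,
                 init$infested_hosts)
})

test_that("infested cells never revert and hosts are conserved", {
  sc <- gen_scenario(scenario_spec(n_rows = 20, n_cols = 20, n_years = 4,
                                   survey_effort = 50, seed = 3))
  for (s in c(1, 2)) {
    set.seed(s)
    run <- simulate_spread(sc$init, sc$landscape, sc$weather, sc$true_params,
                           sc$network, sc$sim_config)
    for (k in seq_along(run$years)) {
      st <- run$states[[k]]
      expect_true(all(st$infested_hosts <= sc$landscape$host_total))
      expect_true(all(st$groups >= 0))
      if (k > 1) {
        prev <- run$infested[[k - 1]]
        expect_true(all(run$infested[[k]][prev]))  # monotone growth
        # psi accounts exactly for the year's newly infested hosts
        expect_equal(sum(attr(st, "psi")),
                     sum(st$infested_hosts) -
                       sum(run$states[[k - 1]]$infested_hosts))
      }
    }
  }
})

test_that("short-range kernels keep establishments near the source", {
  L <- flat_landscape(21, 21, hosts = 50)
  W <- flat_weather(21, 21)
  init <- initial_state(L, c(11, 11), 2020, groups = 40)
  set.seed(14)
  run <- simulate_spread(init, L, W, slf_params(3, 100, 1, 1, 2), NULL,
                         slf_sim_config(2021, 1))
  # weight by newly established groups: the heavy tail scatters a few rare
  # long jumps, but the mass of establishments stays next to the source
  psi <- attr(run$states[["2021"]], "psi")
  est <- which(psi > 0, arr.ind = TRUE)
  w <- psi[psi > 0]
  cheb <- pmax(abs(est[, 1] - 11), abs(est[, 2] - 11))
  expect_gte(sum(w[cheb <= 1]) / sum(w), 0.9)
})

test_that("gamma = 1 never uses the rail network", {
  sc <- gen_scenario(scenario_spec(n_rows = 20, n_cols = 20, n_years = 4,
                                   survey_effort = 50, seed = 4))
  p1 <- slf_params(2, 2500, 1, 2e4, 1e5)
  set.seed(15)
  st <- sc$init
  ctx <- slfspread:::build_sim_ctx(sc$landscape, sc$weather, sc$network,
                                   sc$sim_config)
  for (k in 1:3) {
    st <- step_year(st, sc$landscape, sc$weather, sc$network, p1,
                    sc$sim_config, ctx = ctx)
    expect_equal(attr(st, "n_network_events"), 0L)
  }
  # with no rail anywhere, gamma = 0 behaves exactly like gamma = 1
  p0 <- slf_params(2, 2500, 0, 2e4, 1e5)
  set.seed(16)
  a <- simulate_spread(sc$init, sc$landscape, sc$weather, p0, NULL,
                       sc$sim_config)
  set.seed(16)
  b <- simulate_spread(sc$init, sc$landscape, sc$weather, p1, NULL,
                       sc$sim_config)
  expect_identical(a$infested, b$infested)
})

test_that("identical inputs and seed give identical trajectories", {
  sc <- gen_scenario(scenario_spec(n_rows = 20, n_cols = 20, n_years = 4,
                                   survey_effort = 50, seed = 5))
  set.seed(99)
  a <- simulate_spread(sc$init, sc$landscape, sc$weather, sc$true_params,
                       sc$network, sc$sim_config)
  set.seed(99)
  b <- simulate_spread(sc$init, sc$landscape, sc$weather, sc$true_params,
                       sc$network, sc$sim_config)
  expect_identical(a$states, b$states)
})

test_that("monthly stepping honours the season mask", {
  L <- flat_landscape(6, 6); W <- flat_weather(6, 6, tc = 1,
                                               mask = default_season_mask())
  init <- initial_state(L, c(3, 3), 2020, groups = 5)
  set.seed(17)
  st <- step_year(init, L, W, NULL, slf_params(1, 1000, 1, 1, 2),
                  slf_sim_config(2021, 12))
  expect_equal(st$year, 2021L)
  expect_true(sum(st$groups) >= sum(init$groups))
})
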