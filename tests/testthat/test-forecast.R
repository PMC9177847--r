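test_that("ensemble probability is the infested-run fraction, exactly", {
  L <- flat_landscape(4, 4)
  W <- flat_weather(4, 4)
  init <- initial_state(L, c(2, 2), 2020, groups = 2)
  # beta = 0: nothing spreads, so probability equals the initial indicator
  set.seed(31)
  ens <- run_ensemble(init, L, W, slf_params(0, 1000, 1, 100, 200), NULL,
                      slf_sim_config(2023, 1), n_runs = 37)
  ind <- (init$infested_hosts >= 1) * 1
  for (k in seq_along(ens$years)) expect_equal(ens$prob[, , k], ind)
  # an initially infested cell has probability exactly 1 in every year
  set.seed(32)
  sc <- gen_scenario(scenario_spec(n_rows = 16, n_cols = 16, n_years = 3,
                                   survey_effort = 50, seed = 7))
  cfg <- sc$sim_config; cfg$end_year <- sc$init$year + 4L
  ens2 <- run_ensemble(sc$init, sc$landscape, sc$weather, sc$true_params,
                       sc$network, cfg, n_runs = 40)
  intro <- which(sc$init$infested_hosts >= 1)
  for (k in seq_along(ens2$years))
    expect_equal(ens2$prob[, , k][intro], rep(1, length(intro)))
  # probabilities are exact multiples of 1/n_runs, in [0, 1], monotone in year
  expect_true(all(abs(ens2$prob * 40 - round(ens2$prob * 40)) < 1e-12))
  expect_true(all(ens2$prob >= 0 & ens2$prob <= 1))
  for (k in seq_along(ens2$years)[-1])
    expect_true(all(ens2$prob[, , k] >= ens2$prob[, , k - 1]))
})

test_that("independent large ensembles agree within binomial error", {
  sc <- gen_scenario(scenario_spec(n_rows = 12, n_cols = 12, n_years = 2,
                                   survey_effort = 50, seed = 8))
  cfg <- sc$sim_config
  n <- 1500
  set.seed(33)
  a <- run_ensemble(sc$init, sc$landscape, sc$weather, sc$true_params,
                    sc$network, cfg, n_runs = n)
  set.seed(34)
  b <- run_ensemble(sc$init, sc$landscape, sc$weather, sc$true_params,
                    sc$network, cfg, n_runs = n)
  k <- length(a$years)
  p <- (a$prob[, , k] + b$prob[, , k]) / 2
  se <- sqrt(pmax(p * (1 - p), 1e-6) * 2 / n)
  ok <- abs(a$prob[, , k] - b$prob[, , k]) < 3 * se + 1e-12
  expect_gte(mean(ok), 0.99)
})

test_that("posterior forecasts draw parameter uncertainty per run", {
  post <- data.frame(beta = c(0, 3), alpha1 = c(1000, 3000),
                     gamma = c(1, 1), d_min = c(100, 100),
                     d_max = c(200, 200),
                     accuracy = 1, precision = 1, recall = 1, specificity = 1)
  L <- flat_landscape(8, 8, hosts = 20)
  init <- initial_state(L, c(4, 4), 2020, groups = 10)
  set.seed(35)
  ens <- run_ensemble(init, L, flat_weather(8, 8), post, NULL,
                      slf_sim_config(2022, 1), n_runs = 60)
  # beta = 3 runs spread beyond the intro cell, so some cell other than the
  # introduction must carry positive probability
  expect_gt(sum(ens$prob[, , 3] > 0), 1)
})

test_that("downscaling replicates blocks and masks hostless fine pixels", {
  coarse <- matrix(c(0.6, 0.2, 0, 1), 2, 2)
  host_all <- matrix(1, 4, 4)
  fine <- mask_and_downscale(coarse, host_all, 2)
  expect_equal(dim(fine), c(4L, 4L))
  expect_equal(fine[1:2, 1:2], matrix(0.6, 2, 2))
  expect_equal(fine[3:4, 3:4], matrix(1, 2, 2))
  expect_true(all(mask_and_downscale(coarse, matrix(0, 4, 4), 2) == 0))
  # half the fine pixels of one block hostless: 0.6 survives only on hosts
  host <- matrix(1, 4, 4); host[1, 1:2] <- 0
  fine2 <- mask_and_downscale(coarse, host, 2)
  expect_equal(fine2[1, 1:2], c(0, 0))
  expect_equal(fine2[2, 1:2], c(0.6, 0.6))
  expect_error(mask_and_downscale(coarse, matrix(1, 5, 5), 2), "mismatch")
})

test_that("county aggregation takes zone means and maxima, flagging empties", {
  prob <- matrix(c(0, 0.5, 1, 0.4, 0.4, 0.4), 2, 3)
  zones <- matrix(c(1, 1, 1, 2, 2, 2), 2, 3)
  m <- county_probability(prob, zones, "mean")
  expect_equal(m$value[m$zone == 1], 0.5)
  expect_equal(m$value[m$zone == 2], 0.4)
  mx <- county_probability(prob, zones, "max")
  expect_equal(mx$value, c(1, 0.4))
  miss <- county_probability(prob, zones, "mean", zone_ids = c(1, 2, 7))
  expect_true(is.na(miss$value[miss$zone == 7]))
  expect_error(county_probability(prob, matrix(1, 3, 3)), "aligned")
  # saturation asymptote: all suitable pixels infested, 30% unsuitable
  prob_sat <- matrix(c(rep(1, 7), rep(0, 3)), 1)
  zone_one <- matrix(1, 1, 10)
  expect_equal(county_probability(prob_sat, zone_one, "mean")$value, 0.7)
})

test_that("risk categorisation applies the published boundaries bit-exactly", {
  expect_equal(categorize(0.05), "unsuitable")
  expect_equal(categorize(0.30), "medium")
  expect_equal(categorize(0.99), "high")
  # boundary values belong to the higher category ("below" is strict)
  expect_equal(categorize(c(0.08359, 0.2689, 0.5199)),
               c("low", "medium", "high"))
  expect_equal(categorize(c(0.08359 - 1e-9, 0.2689 - 1e-9, 0.5199 - 1e-9)),
               c("unsuitable", "low", "medium"))
  expect_error(categorize(1.2), "\\[0, 1\\]")
  # monotone step function
  p <- seq(0, 1, by = 0.001)
  lev <- match(categorize(p), c("unsuitable", "low", "medium", "high"))
  expect_true(!is.unsorted(lev))
  # dimensions preserved for rasters
  m <- categorize(matrix(c(0.01, 0.1, 0.3, 0.9), 2, 2))
  expect_equal(dim(m), c(2L, 2L))
})

test_that("map comparison cross-tabulates fractions with exact marginals", {
  a <- c(rep("unsuitable", 4), rep("low", 3), rep("low", 2), "unsuitable")
  b <- c(rep("unsuitable", 4), rep("low", 3), rep("unsuitable", 2), "high")
  cmp <- compare_maps(a, b)
  s <- cmp$summary
  expect_equal(s$both_absent, 0.4)
  expect_equal(s$both_present, 0.3)
  expect_equal(s$a_only, 0.2)
  expect_equal(s$b_only, 0.1)
  expect_equal(sum(cmp$table), 1)
  expect_equal(unname(s$a_only_by_category["low"]), 1)
  expect_equal(unname(s$b_only_by_category["high"]), 1)
  # row/column sums reproduce each map's category marginals exactly
  expect_equal(as.vector(rowSums(cmp$table)),
               as.vector(table(factor(a, slfspread:::risk_levels)) / 10))
  expect_equal(as.vector(colSums(cmp$table)),
               as.vector(table(factor(b, slfspread:::risk_levels)) / 10))
  # identical maps agree everywhere; complementary maps agree nowhere
  ident <- compare_maps(a, a)
  expect_equal(sum(diag(ident$counts)), 10)
  flip <- compare_maps(rep("unsuitable", 4), rep("high", 4))
  expect_equal(sum(diag(flip$counts)), 0)
  expect_error(compare_maps(a, b[1:5]), "aligned")
  expect_error(compare_maps(matrix(a[1:4], 2), matrix(b[1:4], 4)), "aligned")
})
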