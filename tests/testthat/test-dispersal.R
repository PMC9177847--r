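test_that("route choice is Bernoulli(gamma) gated on rail presence", {
  set.seed(1)
  expect_true(all(choose_route(0.5, FALSE, 1000) == "natural"))
  expect_true(all(choose_route(1.0, TRUE, 1000) == "natural"))
  frac_net <- mean(choose_route(0.25, TRUE, 1e5) == "network")
  expect_lt(abs(frac_net - 0.75), 0.01)
  expect_error(choose_route(1.2, TRUE, 10), "gamma")
})

test_that("natural kernel distances follow the half-Cauchy closed form", {
  set.seed(2)
  d <- sample_natural(0, 0, alpha1 = 1000, n = 1e5)$distance
  # median of |Cauchy(0, a)| equals the scale a
  expect_lt(abs(median(d) / 1000 - 1), 0.02)
  # P(d <= a tan(3*pi/8)) = 0.75
  expect_lt(abs(mean(d <= 1000 * tan(3 * pi / 8)) - 0.75), 0.01)
})

test_that("natural kernel bearings are uniform with 0 = North, clockwise", {
  set.seed(3)
  s <- sample_natural(10, -20, alpha1 = 500, n = 1e5)
  # destination is the source displaced by (distance, bearing)
  rad <- s$bearing * pi / 180
  expect_equal(s$x, 10 + s$distance * sin(rad))
  expect_equal(s$y, -20 + s$distance * cos(rad))
  # bearing 0 displaces north (+y), bearing 90 east (+x)
  north <- s[abs(s$bearing) < 1 | s$bearing > 359, ]
  expect_true(all(north$y > -20))
  # uniformity: chi-squared over 36 bins
  p <- chisq.test(table(cut(s$bearing, seq(0, 360, by = 10))))$p.value
  expect_gt(p, 0.01)
})

test_that("network travel starting at a node rides away deterministically", {
  net <- line_network(10000)
  set.seed(4)
  # degenerate uniform, no branching: always 3000 m along the edge
  for (i in 1:5) {
    res <- sample_network(net, edge = 1, arc_pos = 0, d_min = 3000, d_max = 3000)
    expect_equal(res$x, 3000)
    expect_equal(res$y, -2500)
    expect_equal(res$distance, 3000)
  }
  # a draw exceeding the network stops at the dead end (node B)
  res <- sample_network(net, edge = 1, arc_pos = 0, d_min = 2e4, d_max = 2e4)
  expect_equal(c(res$x, res$y), c(10000, -2500))
  expect_equal(res$distance, 10000)
  expect_error(sample_network(net, 1, 10001, 100, 100), "not on any edge")
  expect_error(sample_network(net, 5, 0, 100, 100), "not on any edge")
})

test_that("a rider at a Y junction reaches each arm midpoint equally often", {
  net <- y_network(arm = 5000)
  set.seed(5)
  n <- 2e4
  hits <- matrix(0, n, 2)
  for (i in seq_len(n)) {
    res <- sample_network(net, edge = 1, arc_pos = 0, d_min = 2500, d_max = 2500)
    hits[i, ] <- c(res$x, res$y)
  }
  mids <- rbind(c(0, 2500), c(-2500 * sqrt(3) / 2, -1250),
                c(2500 * sqrt(3) / 2, -1250))
  freq <- vapply(1:3, function(k)
    mean(abs(hits[, 1] - mids[k, 1]) < 1 & abs(hits[, 2] - mids[k, 2]) < 1), 0)
  expect_equal(sum(freq), 1)
  expect_true(all(abs(freq - 1 / 3) < 0.02))
})

test_that("mid-edge travel distances are Uniform(d_min, d_max) off dead ends", {
  net <- line_network(4e5)
  set.seed(6)
  d <- replicate(1e4, sample_network(net, 1, 2e5, 5000, 20000)$distance)
  ks <- suppressWarnings(ks.test(d, "punif", 5000, 20000))
  expect_lt(unname(ks$statistic), 1.63 / sqrt(1e4))  # 1% critical value
})

test_that("boarding uses the nearest within-cell edge position", {
  L <- flat_landscape(3, 3)
  # vertical edge at x = 6500 through cell (2,2), whose centre is (7500,-7500):
  # boarding projects the centre onto the edge
  net <- slf_network(
    nodes = data.frame(id = c("n", "s"), x = c(6500, 6500), y = c(0, -15000)),
    edges = list(list(id = "v", node_a = "n", node_b = "s",
                      verts = rbind(c(6500, 0), c(6500, -15000)))))
  idx <- index_network(net, L)
  ep <- entry_point(c(2, 2), idx)
  p <- slfspread:::point_at(net, ep$edge, ep$arc_pos)
  expect_equal(p, c(6500, -7500))
  expect_error(entry_point(c(1, 3), idx), "no rail")
  # an edge through the exact cell centre boards at the centre
  net2 <- line_network(15000, y0 = -7500)
  idx2 <- index_network(net2, L)
  ep2 <- entry_point(c(2, 2), idx2)
  expect_equal(slfspread:::point_at(net2, ep2$edge, ep2$arc_pos), c(7500, -7500))
  # with two edges in the cell, the nearer one wins
  net3 <- slf_network(
    nodes = data.frame(id = c("a1", "a2", "b1", "b2"),
                       x = c(0, 15000, 0, 15000),
                       y = c(-7490, -7490, -3000, -3000)),
    edges = list(
      list(id = "near", node_a = "a1", node_b = "a2",
           verts = rbind(c(0, -7490), c(15000, -7490))),
      list(id = "far", node_a = "b1", node_b = "b2",
           verts = rbind(c(0, -3000), c(15000, -3000)))))
  ep3 <- entry_point(c(2, 2), index_network(net3, L))
  expect_equal(ep3$edge, 1L)
})

test_that("network construction validates its geometric invariants", {
  nodes <- data.frame(id = c("A", "B"), x = c(0, 100), y = c(0, 0))
  expect_error(slf_network(nodes, list(list(
    id = "e", node_a = "A", node_b = "C",
    verts = rbind(c(0, 0), c(100, 0))))), "not a declared node")
  expect_error(slf_network(nodes, list(list(
    id = "e", node_a = "A", node_b = "B",
    verts = rbind(c(0, 5), c(100, 0))))), "start/end")
  expect_error(slf_network(nodes, list(list(
    id = "e", node_a = "A", node_b = "B", length = 500,
    verts = rbind(c(0, 0), c(100, 0))))), "declared length")
})

test_that("samplers replay identically under a fixed seed", {
  net <- y_network()
  set.seed(7)
  a <- list(sample_natural(0, 0, 800, 100),
            replicate(50, sample_network(net, 1, 1000, 500, 9000)$distance),
            choose_route(0.5, TRUE, 100))
  set.seed(7)
  b <- list(sample_natural(0, 0, 800, 100),
            replicate(50, sample_network(net, 1, 1000, 500, 9000)$distance),
            choose_route(0.5, TRUE, 100))
  expect_identical(a, b)
})

test_that("the batched walker matches the single-rider sampler", {
  net <- y_network(arm = 5000)
  L <- flat_landscape(3, 3)
  ctx <- slfspread:::build_sim_ctx(L, flat_weather(3, 3), net,
                                   slf_sim_config(2021, 1))
  set.seed(8)
  n <- 5000
  batch <- slfspread:::walk_many(ctx$net_tab, rep(1L, n), rep(1000, n),
                                 500, 9000)
  single <- t(replicate(n, unlist(sample_network(net, 1, 1000, 500, 9000)[c("x", "y")])))
  # same destination distribution (compare x-coordinate ECDFs)
  ks <- suppressWarnings(ks.test(batch[, 1], single[, 1]))
  expect_gt(ks$p.value, 0.01)
})
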