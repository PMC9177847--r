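# Small fixtures built in code, shared across test files.

# Uniform landscape: every cell has `hosts` host units.
flat_landscape <- function(nr = 5, nc = 5, hosts = 10, cell_size = 5000) {
  slf_landscape(matrix(hosts, nr, nc), cell_size = cell_size, origin = c(0, 0))
}

# Constant weather: coefficient `tc` every month, all months active unless a
# mask is given.
flat_weather <- function(nr = 5, nc = 5, tc = 1, mask = rep(1L, 12)) {
  slf_weather(array(tc, dim = c(nr, nc, 12)), mask)
}

# One straight horizontal edge A -> B of the given length, through y = y0.
line_network <- function(length_m = 10000, y0 = -2500, x0 = 0) {
  slf_network(
    nodes = data.frame(id = c("A", "B"), x = c(x0, x0 + length_m),
                       y = c(y0, y0)),
    edges = list(list(id = "AB", node_a = "A", node_b = "B",
                      verts = rbind(c(x0, y0), c(x0 + length_m, y0)))))
}

# Y-shaped network: hub at (0, 0) with three straight arms of equal length.
y_network <- function(arm = 5000) {
  tips <- rbind(N = c(0, arm),
                SW = c(-arm * sqrt(3) / 2, -arm / 2),
                SE = c(arm * sqrt(3) / 2, -arm / 2))
  slf_network(
    nodes = data.frame(id = c("hub", "tN", "tSW", "tSE"),
                       x = c(0, tips[, 1]), y = c(0, tips[, 2])),
    edges = list(
      list(id = "eN", node_a = "hub", node_b = "tN",
           verts = rbind(c(0, 0), tips["N", ])),
      list(id = "eSW", node_a = "hub", node_b = "tSW",
           verts = rbind(c(0, 0), tips["SW", ])),
      list(id = "eSE", node_a = "hub", node_b = "tSE",
           verts = rbind(c(0, 0), tips["SE", ]))))
}

# A minimal simulated run object with prescribed infested matrices.
manual_run <- function(infested_by_year) {
  years <- as.integer(names(infested_by_year))
  structure(list(states = NULL, infested = infested_by_year, years = years,
                 params = NULL, config = NULL), class = "slf_run")
}

stat_vec <- function(s) c(s$accuracy, s$precision, s$recall, s$specificity)

# Deterministic accuracy stub whose four statistics are a known function of
# beta; used to check the ABC acceptance region analytically.
beta_stub <- function(f) function(p) {
  v <- f(p[["beta"]])
  structure(list(accuracy = v, precision = v, recall = v, specificity = v,
                 counts = c(tp = 1, fp = 0, fn = 0, tn = 1),
                 undefined = character()), class = "slf_accuracy")
}
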