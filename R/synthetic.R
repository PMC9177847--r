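#' Synthetic scenario specification
#'
#' Describes a fully synthetic study system with known ground truth: a patchy
#' host landscape, a rail network crossing it, smooth seasonal weather, a
#' seeded introduction spread under known parameters, and imperfect spatially
#' clustered presence/absence surveys. It emulates the *structure* of real
#' pest-survey campaigns (clustered effort near known infestations, false
#' negatives, background negatives) without any real geography.
#'
#' @param n_rows,n_cols grid dimensions (at least 8 x 8).
#' @param cell_size cell edge in metres.
#' @param host_cover fraction of host-positive cells, in \[0, 1\].
#' @param patchiness smoothing length of the host random field, in cells.
#' @param carrying_units host units in a fully suitable cell.
#' @param rail_topology `"line"`, `"Y"`, or `"lattice"`.
#' @param rail_spacing lattice line spacing in cells.
#' @param true_params the known `slf_params` that generate the truth.
#' @param intro_cell (row, col) of the introduction, or `NULL` to pick a
#'   host-positive rail cell near the grid centre.
#' @param intro_year calendar year of the introduction.
#' @param intro_groups pest groups seeded in the introduction cell.
#' @param n_years number of simulated/surveyed years (introduction year
#'   inclusive).
#' @param survey_effort survey records per year.
#' @param survey_clustering standard deviation, in cells, of survey placement
#'   around infested cells.
#' @param cluster_fraction fraction of effort targeted near infested cells;
#'   the rest is uniform background.
#' @param false_negative_rate probability an infested surveyed cell is
#'   recorded negative.
#' @param sub_steps simulation stepping for the true run (1 or 12).
#' @param seed RNG seed making the whole bundle reproducible.
#' @return an object of class `scenario_spec`.
#' @export
scenario_spec <- function(n_rows = 50L, n_cols = 50L, cell_size = 5000,
                          host_cover = 0.7, patchiness = 3,
                          carrying_units = 100L, rail_topology = "Y",
                          rail_spacing = 10L,
                          true_params = slf_params(beta = 1.5, alpha1 = 2500,
                                                   gamma = 0.9, d_min = 2e4,
                                                   d_max = 1.2e5),
                          intro_cell = NULL, intro_year = 2014L,
                          intro_groups = 30L, n_years = 6L,
                          survey_effort = 1000L, survey_clustering = 3,
                          cluster_fraction = 0.3, false_negative_rate = 0.1,
                          sub_steps = 1L, seed = 42L) {
  if (n_rows < 8L || n_cols < 8L) stop("grid must be at least 8 x 8")
  stopifnot(host_cover >= 0, host_cover <= 1,
            false_negative_rate >= 0, false_negative_rate <= 1,
            cluster_fraction >= 0, cluster_fraction <= 1)
  if (!is.null(intro_cell) &&
      (intro_cell[1] > n_rows || intro_cell[2] > n_cols || any(intro_cell < 1)))
    stop("introduction cell outside grid")
  structure(as.list(environment()), class = "scenario_spec")
}

# Gaussian smoothing of a matrix with edge renormalisation (zero-padded
# convolution divided by the kernel mass actually inside the grid).
smooth_matrix <- function(m, sigma) {
  if (sigma <= 0) return(m)
  h <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-h:h, sd = sigma)
  pad_filter <- function(v) {
    y <- stats::filter(c(numeric(h), v, numeric(h)), k, sides = 2)
    w <- stats::filter(c(numeric(h), rep(1, length(v)), numeric(h)), k, sides = 2)
    (y / w)[(h + 1):(h + length(v))]
  }
  m <- apply(m, 2, pad_filter)
  t(apply(t(m), 2, pad_filter))
}

#' Generate a patchy host landscape
#'
#' A smoothed Gaussian random field is thresholded at the quantile giving the
#' requested host cover and rescaled to suitability in (0, 1\]; suitability
#' converts to integer host capacity `N = round(suitability *
#' carrying_units)` with host-positive cells guaranteed at least one unit.
#' Stands in for a niche-model host layer (e.g. tree of heaven suitability).
#'
#' @param spec a `scenario_spec`.
#' @return an `slf_landscape`.
#' @export
gen_landscape <- function(spec) {
  field <- smooth_matrix(matrix(stats::rnorm(spec$n_rows * spec$n_cols),
                                spec$n_rows, spec$n_cols), spec$patchiness)
  if (spec$host_cover == 0) {
    suit <- matrix(0, spec$n_rows, spec$n_cols)
  } else if (spec$host_cover == 1) {
    suit <- 0.2 + 0.8 * (field - min(field)) / max(diff(range(field)), 1e-12)
  } else {
    thr <- stats::quantile(field, 1 - spec$host_cover, names = FALSE)
    suit <- pmax(field - thr, 0)
    if (max(suit) > 0) suit <- suit / max(suit)
  }
  N <- ifelse(suit > 0, pmax(1, round(suit * spec$carrying_units)), 0)
  slf_landscape(N, cell_size = spec$cell_size, origin = c(0, 0))
}

#' Generate smooth seasonal weather coefficients
#'
#' Monthly temperature coefficients follow a bell-shaped seasonal curve
#' peaking mid-season (July), scaled per cell by a smooth field in
#' \[0.8, 1\]; the season mask marks April-October active. The generator
#' produces the monthly coefficient product directly rather than emulating
#' any daily-temperature transform.
#'
#' @param spec a `scenario_spec`.
#' @return an `slf_weather`.
#' @export
gen_weather <- function(spec) {
  profile <- 0.9 * exp(-((1:12 - 7)^2) / (2 * 2.2^2))
  cellf <- smooth_matrix(matrix(stats::rnorm(spec$n_rows * spec$n_cols),
                                spec$n_rows, spec$n_cols), spec$patchiness)
  cellf <- 0.8 + 0.2 * (cellf - min(cellf)) / max(diff(range(cellf)), 1e-12)
  co <- array(0, dim = c(spec$n_rows, spec$n_cols, 12))
  for (m in 1:12) co[, , m] <- pmin(pmax(profile[m] * cellf, 0), 1)
  slf_weather(co, default_season_mask())
}

#' Generate a synthetic rail network
#'
#' Topologies: `"line"` (a gently bent line crossing the grid), `"Y"` (a
#' junction at the grid centre with three arms), `"lattice"` (a sparse grid
#' of straight lines with nodes at the crossings).
#'
#' @param spec a `scenario_spec`.
#' @return an `slf_network`.
#' @export
gen_network <- function(spec) {
  W <- spec$n_cols * spec$cell_size; H <- spec$n_rows * spec$cell_size
  cx <- W / 2; cy <- -H / 2
  if (spec$rail_topology == "line") {
    a <- c(0.03 * W, cy + 0.08 * H); b <- c(0.97 * W, cy - 0.08 * H)
    mid <- c(cx, cy + 0.12 * H)
    nodes <- data.frame(id = c("n1", "n2"), x = c(a[1], b[1]),
                        y = c(a[2], b[2]))
    edges <- list(list(id = "e1", node_a = "n1", node_b = "n2",
                       verts = rbind(a, mid, b)))
  } else if (spec$rail_topology == "Y") {
    arm <- 0.45 * min(W, H)
    tipN <- c(cx, cy + arm); tipSW <- c(cx - arm * 0.87, cy - arm * 0.5)
    tipSE <- c(cx + arm * 0.87, cy - arm * 0.5)
    nodes <- data.frame(id = c("hub", "tN", "tSW", "tSE"),
                        x = c(cx, tipN[1], tipSW[1], tipSE[1]),
                        y = c(cy, tipN[2], tipSW[2], tipSE[2]))
    bend <- function(tip, s) {
      m <- (c(cx, cy) + tip) / 2
      perp <- c(-(tip[2] - cy), tip[1] - cx)
      m + s * 0.06 * perp
    }
    edges <- list(
      list(id = "eN", node_a = "hub", node_b = "tN",
           verts = rbind(c(cx, cy), bend(tipN, 1), tipN)),
      list(id = "eSW", node_a = "hub", node_b = "tSW",
           verts = rbind(c(cx, cy), bend(tipSW, -1), tipSW)),
      list(id = "eSE", node_a = "hub", node_b = "tSE",
           verts = rbind(c(cx, cy), bend(tipSE, 1), tipSE)))
  } else if (spec$rail_topology == "lattice") {
    s <- spec$rail_spacing * spec$cell_size
    xs <- seq(s, W - s / 2, by = s); ys <- seq(-s, -H + s / 2, by = -s)
    nodes <- expand.grid(xi = seq_along(xs), yi = seq_along(ys))
    nodes <- data.frame(id = paste0("n", nodes$xi, "_", nodes$yi),
                        x = xs[nodes$xi], y = ys[nodes$yi],
                        xi = nodes$xi, yi = nodes$yi)
    edges <- list()
    for (i in seq_len(nrow(nodes))) {
      for (d in list(c(1, 0), c(0, 1))) {
        j <- which(nodes$xi == nodes$xi[i] + d[1] &
                   nodes$yi == nodes$yi[i] + d[2])
        if (length(j))
          edges[[length(edges) + 1L]] <- list(
            id = paste0("e", i, "_", j), node_a = nodes$id[i],
            node_b = nodes$id[j],
            verts = rbind(c(nodes$x[i], nodes$y[i]),
                          c(nodes$x[j], nodes$y[j])))
      }
    }
    nodes <- nodes[, c("id", "x", "y")]
  } else stop("unknown rail topology: ", spec$rail_topology)
  slf_network(nodes, edges)
}

#' Generate imperfect presence/absence surveys from a true run
#'
#' Survey points are placed with spatial clustering near infested areas (a
#' configurable fraction of effort is anchored on infested cells with
#' Gaussian jitter; the rest is uniform background). A record is positive
#' when its cell is truly infested in its year, flipped to negative with the
#' false-negative rate; uninfested cells always yield negatives.
#'
#' @param run the true `slf_run`.
#' @param landscape the `slf_landscape`.
#' @param spec a `scenario_spec`.
#' @return an `slf_observations` data frame.
#' @export
gen_surveys <- function(run, landscape, spec) {
  years <- seq(spec$intro_year, spec$intro_year + spec$n_years - 1L)
  if (!all(years %in% run$years)) stop("true run does not cover survey years")
  W <- landscape$n_cols * landscape$cell_size
  H <- landscape$n_rows * landscape$cell_size
  ox <- landscape$origin[1]; oy <- landscape$origin[2]
  sd_m <- spec$survey_clustering * landscape$cell_size
  out <- list()
  for (y in years) {
    inf <- run$infested[[as.character(y)]]
    inf_cells <- which(inf)
    n <- spec$survey_effort
    n_cl <- if (length(inf_cells)) stats::rbinom(1, n, spec$cluster_fraction) else 0L
    xs <- numeric(n); ys <- numeric(n)
    if (n_cl > 0L) {
      anchors <- inf_cells[sample.int(length(inf_cells), n_cl, replace = TRUE)]
      ar <- ((anchors - 1L) %% landscape$n_rows) + 1L
      ac <- ((anchors - 1L) %/% landscape$n_rows) + 1L
      ctr <- cell_center(ar, ac, landscape)
      px <- ctr[, 1] + stats::rnorm(n_cl, 0, sd_m)
      py <- ctr[, 2] + stats::rnorm(n_cl, 0, sd_m)
      # clamp jittered points just inside the grid
      eps <- landscape$cell_size * 1e-6
      xs[seq_len(n_cl)] <- pmin(pmax(px, ox + eps), ox + W - eps)
      ys[seq_len(n_cl)] <- pmin(pmax(py, oy - H + eps), oy - eps)
    }
    if (n_cl < n) {
      bg <- seq(n_cl + 1L, n)
      xs[bg] <- stats::runif(length(bg), ox, ox + W)
      ys[bg] <- stats::runif(length(bg), oy - H, oy)
    }
    rc <- cell_of(xs, ys, landscape)
    truly <- inf[rc]
    status <- ifelse(truly & stats::runif(n) >= spec$false_negative_rate,
                     "positive", "negative")
    out[[length(out) + 1L]] <- data.frame(x = xs, y = ys, year = y,
                                          status = status)
  }
  slf_observations(do.call(rbind, out), landscape)
}

#' Generate a complete synthetic scenario bundle
#'
#' Seeds the RNG from the spec and builds, in order: landscape, weather,
#' rail network, introduction state, the true spread run under the true
#' parameters, and the surveys. Identical spec (including seed) gives an
#' identical bundle.
#'
#' @param spec a `scenario_spec`.
#' @return an object of class `slf_scenario`: `spec`, `landscape`,
#'   `weather`, `network`, `init`, `sim_config`, `true_params`, `true_run`,
#'   `surveys`.
#' @export
gen_scenario <- function(spec) {
  set.seed(spec$seed)
  landscape <- gen_landscape(spec)
  weather <- gen_weather(spec)
  network <- gen_network(spec)
  intro <- spec$intro_cell
  if (is.null(intro)) {
    ni <- index_network(network, landscape)
    cand <- which(ni$has_rail & landscape$host_total > 0)
    if (!length(cand)) cand <- which(landscape$host_total > 0)
    if (!length(cand)) stop("no host-positive cell to introduce into")
    cr <- ((cand - 1L) %% landscape$n_rows) + 1L
    cc <- ((cand - 1L) %/% landscape$n_rows) + 1L
    # prefer a host-rich cell near the grid centre: introductions take hold
    # where propagule pressure meets abundant hosts
    d2 <- (cr - landscape$n_rows / 2)^2 + (cc - landscape$n_cols / 2)^2
    r2 <- (max(landscape$n_rows, landscape$n_cols) / 6)^2
    near <- d2 <= max(r2, min(d2))
    k <- which(near)[which.max(landscape$host_total[cand[near]])]
    intro <- c(cr[k], cc[k])
  }
  if (landscape$host_total[intro[1], intro[2]] == 0)
    stop("introduction cell has no hosts")
  init <- initial_state(landscape, intro, spec$intro_year,
                        groups = spec$intro_groups)
  sim_config <- slf_sim_config(end_year = spec$intro_year + spec$n_years - 1L,
                               sub_steps = spec$sub_steps)
  true_run <- simulate_spread(init, landscape, weather, spec$true_params,
                              network, sim_config)
  surveys <- gen_surveys(true_run, landscape, spec)
  structure(list(spec = spec, landscape = landscape, weather = weather,
                 network = network, init = init, sim_config = sim_config,
                 true_params = spec$true_params, true_run = true_run,
                 surveys = surveys),
            class = "slf_scenario")
}

#' @export
print.slf_scenario <- function(x, ...) {
  cat(sprintf("slf_scenario: %dx%d grid, %s rail, years %d-%d, seed %d\n",
              x$spec$n_rows, x$spec$n_cols, x$spec$rail_topology,
              x$spec$intro_year, x$sim_config$end_year, x$spec$seed))
  cat(sprintf("  surveys: %d records (%d positive)\n", nrow(x$surveys),
              sum(x$surveys$status == "positive")))
  cat(sprintf("  true infested cells, final year: %d\n",
              sum(x$true_run$infested[[length(x$true_run$infested)]])))
  invisible(x)
}
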