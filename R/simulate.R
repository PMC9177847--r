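#' Simulation configuration
#'
#' @param end_year last calendar year simulated (inclusive).
#' @param sub_steps internal steps per year: 12 (monthly, using the monthly
#'   temperature coefficients gated by the season mask) or 1 (a single yearly
#'   step using the mean active-month coefficient). With yearly stepping,
#'   `beta` is interpreted per year rather than per month.
#' @param apply_T_at_reproduction,apply_T_at_establishment whether the
#'   temperature coefficient modulates the reproductive rate and the
#'   establishment probability. The model applies the environment at both
#'   stages by default.
#' @return an object of class `slf_sim_config`.
#' @export
slf_sim_config <- function(end_year, sub_steps = 12L,
                           apply_T_at_reproduction = TRUE,
                           apply_T_at_establishment = TRUE) {
  if (!sub_steps %in% c(1L, 12L)) stop("sub_steps must be 1 or 12")
  structure(list(end_year = end_year, sub_steps = as.integer(sub_steps),
                 apply_T_at_reproduction = isTRUE(apply_T_at_reproduction),
                 apply_T_at_establishment = isTRUE(apply_T_at_establishment)),
            class = "slf_sim_config")
}

# Precompute per-weather matrices: monthly coefficient matrices for active
# months and the mean active-month coefficient for yearly stepping.
prep_weather <- function(weather) {
  active <- which(weather$season_mask == 1L)
  Tm <- lapply(seq_len(12L), function(m) weather$coefficients[, , m])
  Tbar <- Reduce(`+`, Tm[active]) / max(length(active), 1L)
  list(Tm = Tm, active = active, Tbar = Tbar)
}

# Simulation context shared across steps: landscape geometry, host counts,
# rail lookup tables and prepped weather.
build_sim_ctx <- function(landscape, weather, network, config) {
  nr <- landscape$n_rows; nc <- landscape$n_cols
  ncell <- nr * nc
  entry_edge <- rep(NA_integer_, ncell)
  entry_pos <- rep(NA_real_, ncell)
  has_rail <- matrix(FALSE, nr, nc)
  if (!is.null(network)) {
    ni <- index_network(network, landscape)
    has_rail <- ni$has_rail
    idx <- ni$index
    if (nrow(idx)) {
      lin <- (idx$col - 1L) * nr + idx$row
      ord <- order(lin, idx$dist)  # nearest edge first within each cell
      idx <- idx[ord, ]; lin <- lin[ord]
      first <- !duplicated(lin)
      entry_edge[lin[first]] <- idx$edge[first]
      entry_pos[lin[first]] <- idx$arc_pos[first]
    }
  }
  ws <- if (inherits(weather, "slf_weather")) list(prep_weather(weather))
  else lapply(weather, prep_weather)
  net_tab <- if (!is.null(network)) {
    nid <- network$nodes$id
    list(len = vapply(network$edges, `[[`, 0, "length"),
         node_a = match(vapply(network$edges, `[[`, "", "node_a"), nid),
         node_b = match(vapply(network$edges, `[[`, "", "node_b"), nid),
         adj = unname(network$adjacency),
         verts = lapply(network$edges, `[[`, "verts"),
         cum = lapply(network$edges, `[[`, "cum"))
  }
  list(nr = nr, nc = nc, ncell = ncell, cs = landscape$cell_size,
       net_tab = net_tab,
       ox = landscape$origin[1], oy = landscape$origin[2],
       Nvec = as.vector(landscape$host_total), maxN = max(landscape$host_total, 1),
       has_rail = has_rail, entry_edge = entry_edge, entry_pos = entry_pos,
       network = network, weather = ws, config = config)
}

# Batched rail walker over the flat network tables in the simulation
# context; semantically identical to sample_network() (uniform travel
# distance, uniform initial direction, uniform branch choice excluding the
# arrival edge, dead-end stop, mid-edge disembarkation) but avoids per-rider
# list traversal in the inner simulation loop.
walk_many <- function(tab, ei_vec, pos_vec, d_min, d_max) {
  n <- length(ei_vec)
  drawn <- stats::runif(n, d_min, d_max)
  dirs <- c(-1, 1)[1L + (stats::runif(n) < 0.5)]
  lens <- tab$len; nodes_a <- tab$node_a; nodes_b <- tab$node_b
  adj <- tab$adj
  out <- matrix(0, n, 2)
  for (i in seq_len(n)) {
    ei <- ei_vec[i]; pos <- pos_vec[i]; dir <- dirs[i]; rem <- drawn[i]
    if (pos <= 0 || pos >= lens[ei]) {
      # node start: choose uniformly among the node's incident edges
      node <- if (pos <= 0) nodes_a[ei] else nodes_b[ei]
      inc <- adj[[node]]
      ei <- inc[1L + floor(stats::runif(1) * length(inc))]
      if (nodes_a[ei] == node) { pos <- 0; dir <- 1 }
      else { pos <- lens[ei]; dir <- -1 }
    }
    repeat {
      L <- lens[ei]
      to_end <- if (dir > 0) L - pos else pos
      if (rem <= to_end) { fin <- pos + dir * rem; break }
      rem <- rem - to_end
      node <- if (dir > 0) nodes_b[ei] else nodes_a[ei]
      nxt <- adj[[node]]
      nxt <- nxt[nxt != ei]
      m <- length(nxt)
      if (!m) { fin <- if (dir > 0) L else 0; break }
      ei <- if (m == 1L) nxt else nxt[1L + floor(stats::runif(1) * m)]
      if (nodes_a[ei] == node) { pos <- 0; dir <- 1 }
      else { pos <- lens[ei]; dir <- -1 }
    }
    cum <- tab$cum[[ei]]; v <- tab$verts[[ei]]
    if (fin < 0) fin <- 0 else if (fin > lens[ei]) fin <- lens[ei]
    k <- 1L
    while (fin > cum[k + 1L] && k < length(cum) - 1L) k <- k + 1L
    f <- (fin - cum[k]) / (cum[k + 1L] - cum[k])
    out[i, 1] <- v[k, 1] + f * (v[k + 1L, 1] - v[k, 1])
    out[i, 2] <- v[k, 2] + f * (v[k + 1L, 2] - v[k, 2])
  }
  out
}

# One reproduction-dispersal-establishment sweep. `Tmat` is the temperature
# coefficient matrix for the step. Returns updated groups/infested and the
# per-cell count of newly infested hosts (psi).
step_once <- function(groups, infested, Tmat, params, ctx) {
  cfg <- ctx$config
  src <- which(groups > 0L)
  psi <- integer(ctx$ncell)
  if (!length(src))
    return(list(groups = groups, infested = infested, psi = psi, n_net = 0L))
  lam <- params$beta * (if (cfg$apply_T_at_reproduction) Tmat[src] else 1)
  nd <- stats::rpois(length(src), groups[src] * lam)
  tot <- sum(nd)
  if (tot == 0L)
    return(list(groups = groups, infested = infested, psi = psi, n_net = 0L))
  src_rep <- rep.int(src, nd)
  rows <- ((src_rep - 1L) %% ctx$nr) + 1L
  cols <- ((src_rep - 1L) %/% ctx$nr) + 1L
  cx <- ctx$ox + (cols - 0.5) * ctx$cs
  cy <- ctx$oy - (rows - 0.5) * ctx$cs
  use_net <- ctx$has_rail[src_rep] & stats::runif(tot) >= params$gamma &
    !is.null(ctx$network)
  dx <- numeric(tot); dy <- numeric(tot)
  nat <- which(!use_net)
  if (length(nat)) {
    d <- abs(stats::rcauchy(length(nat), 0, params$alpha1))
    th <- stats::runif(length(nat), 0, 2 * pi)
    dx[nat] <- cx[nat] + d * sin(th)
    dy[nat] <- cy[nat] + d * cos(th)
  }
  riders <- which(use_net)
  n_net <- length(riders)
  if (n_net) {
    dest <- walk_many(ctx$net_tab, ctx$entry_edge[src_rep[riders]],
                      ctx$entry_pos[src_rep[riders]], params$d_min, params$d_max)
    dx[riders] <- dest[, 1]; dy[riders] <- dest[, 2]
  }
  # destination cells; out-of-bounds dispersers are lost
  colD <- floor((dx - ctx$ox) / ctx$cs)
  rowD <- floor((ctx$oy - dy) / ctx$cs)
  ok <- colD >= 0 & colD < ctx$nc & rowD >= 0 & rowD < ctx$nr
  dd <- colD[ok] * ctx$nr + rowD[ok] + 1L
  if (length(dd)) {
    # environment gate at establishment
    if (cfg$apply_T_at_establishment) dd <- dd[stats::runif(length(dd)) < Tmat[dd]]
  }
  if (length(dd)) {
    Nv <- ctx$Nvec[dd]
    pos <- Nv > 0
    dd <- dd[pos]; Nv <- Nv[pos]
    if (length(dd)) {
      # Each arrival picks a uniform host slot in its cell; it establishes iff
      # the slot is susceptible and it is the first arrival to hit that slot.
      # This reproduces the sequential Bernoulli(S/N) draws with S depleting
      # by one per success, vectorised across cells.
      Sv <- Nv - infested[dd]
      slot <- ceiling(stats::runif(length(dd)) * Nv)
      est <- slot <= Sv
      ci <- which(est)
      if (length(ci) > 1L) {
        key <- (dd[ci] - 1) * ctx$maxN + slot[ci]
        est[ci[duplicated(key)]] <- FALSE
      }
      if (any(est)) {
        add <- tabulate(dd[est], nbins = ctx$ncell)
        groups <- groups + add
        infested <- infested + add
        psi <- add
      }
    }
  }
  list(groups = groups, infested = infested, psi = psi, n_net = n_net)
}

#' Draw dispersers produced by one reproduction step
#'
#' For a cell holding `g` pest groups the number of dispersing offspring
#' groups is the sum of `g` independent Poisson draws with rate
#' `modified_rate(beta, T, X)` — equivalently one Poisson draw with rate
#' `g * beta * T * X`. Months outside the season mask produce no dispersers.
#'
#' @param state an `slf_state`.
#' @param landscape an `slf_landscape`.
#' @param weather an `slf_weather`.
#' @param params an `slf_params`.
#' @param month month index 1-12.
#' @return integer matrix of disperser counts per cell.
#' @export
reproduce <- function(state, landscape, weather, params, month) {
  X <- weather$season_mask[month]
  if (X == 0L) return(matrix(0L, landscape$n_rows, landscape$n_cols))
  lam <- modified_rate(params$beta, weather$coefficients[, , month], X)
  out <- stats::rpois(length(state$groups), state$groups * lam)
  matrix(as.integer(out), landscape$n_rows, landscape$n_cols)
}

#' Attempt establishment of a dispersing group in a cell
#'
#' Establishment succeeds with probability `(S/N) * T * X` where `S` is the
#' cell's susceptible host count, `N` its total host count, `T` the month's
#' temperature coefficient and `X` the season flag; cells with no hosts never
#' establish. On success the cell gains one pest group and one host unit moves
#' from susceptible to infested.
#'
#' @param cell length-2 vector (row, col), 1-based.
#' @inheritParams reproduce
#' @return list with `established` (logical) and the (possibly updated)
#'   `state`.
#' @export
establish <- function(cell, landscape, state, weather, month, params = NULL) {
  r <- cell[1]; c <- cell[2]
  if (r < 1 || r > landscape$n_rows || c < 1 || c > landscape$n_cols)
    stop("destination outside the grid")
  N <- landscape$host_total[r, c]
  I <- state$infested_hosts[r, c]
  X <- weather$season_mask[month]
  p <- if (N == 0) 0 else (N - I) / N * weather$coefficients[r, c, month] * X
  hit <- stats::runif(1) < p
  if (hit) {
    state$groups[r, c] <- state$groups[r, c] + 1L
    state$infested_hosts[r, c] <- I + 1L
  }
  list(established = hit, state = state)
}

#' Advance the infestation by one year
#'
#' Runs the reproduction - route choice - dispersal - establishment sweep for
#' each active month (or once with the mean active-month coefficient when
#' `sub_steps = 1`) and returns the state at `year + 1` epoch, i.e. the state
#' after the named year's spread season. Infested cells never revert.
#'
#' @inheritParams reproduce
#' @param network an `slf_network` or `NULL` (no network dispersal).
#' @param config an `slf_sim_config`.
#' @param ctx internal precomputed context; built automatically when `NULL`.
#' @return the next `slf_state`, with attribute `psi` (matrix of hosts newly
#'   infested during the year) and `n_network_events`.
#' @export
step_year <- function(state, landscape, weather, network, params, config,
                      ctx = NULL) {
  if (is.null(ctx)) ctx <- build_sim_ctx(landscape, weather, network, config)
  ws <- ctx$weather[[1L]]
  step_year_ctx(state, params, ctx, ws)
}

step_year_ctx <- function(state, params, ctx, ws) {
  groups <- state$groups; infested <- state$infested_hosts
  psi <- matrix(0L, ctx$nr, ctx$nc)
  n_net <- 0L
  if (ctx$config$sub_steps == 1L) {
    res <- step_once(groups, infested, ws$Tbar, params, ctx)
    groups <- res$groups; infested <- res$infested
    psi <- psi + res$psi; n_net <- n_net + res$n_net
  } else {
    for (m in ws$active) {
      res <- step_once(groups, infested, ws$Tm[[m]], params, ctx)
      groups <- res$groups; infested <- res$infested
      psi <- psi + res$psi; n_net <- n_net + res$n_net
    }
  }
  out <- structure(list(year = state$year + 1L, groups = groups,
                        infested_hosts = infested), class = "slf_state")
  attr(out, "psi") <- psi
  attr(out, "n_network_events") <- n_net
  out
}

#' Simulate spread over a span of years
#'
#' @param init an `slf_state` giving the infestation at the start year.
#' @param landscape an `slf_landscape`.
#' @param weather an `slf_weather` used for every year, or a list of
#'   `slf_weather` realisations with `year_map` selecting one per simulated
#'   year (used by ensemble forecasting to resample historical years).
#' @param params an `slf_params`.
#' @param network an `slf_network` or `NULL`.
#' @param config an `slf_sim_config`; years `init$year + 1` through
#'   `config$end_year` are simulated.
#' @param year_map integer vector, one entry per simulated year, indexing into
#'   the `weather` list; default all 1.
#' @param ctx internal precomputed context (reused across ensemble runs).
#' @return an object of class `slf_run`: yearly state snapshots (named by
#'   year; the entry for year `y` is the state after year `y`'s season) and
#'   per-year infested-cell indicator matrices.
#' @export
simulate_spread <- function(init, landscape, weather, params, network = NULL,
                            config, year_map = NULL, ctx = NULL) {
  if (is.null(ctx)) ctx <- build_sim_ctx(landscape, weather, network, config)
  years <- seq(init$year, config$end_year)
  n_sim <- length(years) - 1L
  if (is.null(year_map)) year_map <- rep(1L, max(n_sim, 0L))
  states <- vector("list", length(years))
  names(states) <- as.character(years)
  states[[1L]] <- init
  st <- init
  for (k in seq_len(n_sim)) {
    st <- step_year_ctx(st, params, ctx, ctx$weather[[year_map[k]]])
    states[[k + 1L]] <- st
  }
  infested <- lapply(states, function(s) s$infested_hosts >= 1L)
  structure(list(states = states, infested = infested, years = years,
                 params = params, config = config), class = "slf_run")
}

#' @export
print.slf_run <- function(x, ...) {
  n_inf <- vapply(x$infested, sum, 0L)
  cat(sprintf("slf_run: years %d-%d; infested cells per year: %s\n",
              min(x$years), max(x$years), paste(n_inf, collapse = " ")))
  invisible(x)
}
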