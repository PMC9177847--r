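#' Raster landscape of host availability
#'
#' The landscape is a regular grid in projected metre coordinates. The origin
#' is the upper-left corner of the grid; x increases eastward and y decreases
#' southward. Each cell carries an integer number of potential host units `N`
#' (total) of which `S` are initially susceptible; during a simulation the
#' susceptible count of a cell is `N - I` where `I` is the infested-host count
#' held by the simulation state.
#'
#' @param host_total integer matrix (`n_rows` x `n_cols`) of potential host
#'   units `N` per cell. Non-negative.
#' @param host_susceptible integer matrix of initially susceptible host units
#'   `S`; defaults to `host_total`. Must satisfy `0 <= S <= N` cellwise.
#' @param cell_size cell edge length in metres (default 5000).
#' @param origin numeric `(x, y)` of the grid's upper-left corner in metres.
#' @return an object of class `slf_landscape`.
#' @seealso [landscape_from_suitability()], [cell_of()], [cell_center()]
#' @export
slf_landscape <- function(host_total, host_susceptible = host_total,
                          cell_size = 5000, origin = c(0, 0)) {
  host_total <- as.matrix(host_total)
  host_susceptible <- as.matrix(host_susceptible)
  if (nrow(host_total) < 1L || ncol(host_total) < 1L)
    stop("landscape must have at least one row and one column")
  if (!identical(dim(host_total), dim(host_susceptible)))
    stop("host_total and host_susceptible dimensions differ")
  if (any(host_total < 0)) stop("host_total must be non-negative")
  if (any(host_susceptible < 0) || any(host_susceptible > host_total))
    stop("host_susceptible must satisfy 0 <= S <= N cellwise")
  if (!is.numeric(cell_size) || length(cell_size) != 1L || cell_size <= 0)
    stop("cell_size must be a positive scalar (metres)")
  if (length(origin) != 2L) stop("origin must be (x, y)")
  structure(list(
    n_rows = nrow(host_total), n_cols = ncol(host_total),
    cell_size = as.numeric(cell_size), origin = as.numeric(origin),
    host_total = round(host_total), host_susceptible = round(host_susceptible)
  ), class = "slf_landscape")
}

#' Convert a suitability surface to a host landscape
#'
#' Host layers often arrive as a suitability probability in \[0, 1\] (e.g. a
#' niche-model output for tree of heaven). The count-based spread model needs
#' integer host capacities, so suitability is converted to
#' `N = round(suitability * carrying_units)`.
#'
#' @param suitability numeric matrix with values in \[0, 1\].
#' @param carrying_units host units in a fully suitable cell (default 100).
#' @inheritParams slf_landscape
#' @return an `slf_landscape`.
#' @export
landscape_from_suitability <- function(suitability, carrying_units = 100,
                                       cell_size = 5000, origin = c(0, 0)) {
  suitability <- as.matrix(suitability)
  if (any(suitability < 0) || any(suitability > 1))
    stop("suitability values must lie in [0, 1]")
  slf_landscape(round(suitability * carrying_units),
                cell_size = cell_size, origin = origin)
}

#' @export
print.slf_landscape <- function(x, ...) {
  cat(sprintf("slf_landscape: %d x %d cells of %g m\n", x$n_rows, x$n_cols,
              x$cell_size))
  cat(sprintf("  origin (upper-left): (%g, %g) m\n", x$origin[1], x$origin[2]))
  cat(sprintf("  host-positive cells: %d of %d (total host units %g)\n",
              sum(x$host_total > 0), x$n_rows * x$n_cols, sum(x$host_total)))
  invisible(x)
}

#' Monthly weather coefficients and season mask
#'
#' Temperature enters the model as a monthly coefficient `T` in \[0, 1\] per
#' cell (1 = optimal), and seasonality as a binary month mask `X`: months with
#' `X = 0` contribute no reproduction or establishment. The default mask marks
#' April-October active, the usual spotted-lanternfly activity season.
#'
#' @param coefficients 3-d array (`n_rows` x `n_cols` x 12) of monthly
#'   coefficients in \[0, 1\], or a single matrix recycled to all 12 months.
#' @param season_mask integer vector of 12 zeros/ones.
#' @return an object of class `slf_weather`.
#' @export
slf_weather <- function(coefficients, season_mask = default_season_mask()) {
  if (is.matrix(coefficients))
    coefficients <- array(rep(coefficients, 12L), dim = c(dim(coefficients), 12L))
  if (length(dim(coefficients)) != 3L || dim(coefficients)[3] != 12L)
    stop("coefficients must be an n_rows x n_cols x 12 array")
  if (any(coefficients < 0) || any(coefficients > 1))
    stop("temperature coefficients must lie in [0, 1]")
  season_mask <- as.integer(season_mask)
  if (length(season_mask) != 12L || !all(season_mask %in% c(0L, 1L)))
    stop("season_mask must be 12 values in {0, 1}")
  structure(list(coefficients = coefficients, season_mask = season_mask),
            class = "slf_weather")
}

#' @rdname slf_weather
#' @export
default_season_mask <- function() {
  m <- integer(12)
  m[4:10] <- 1L
  m
}

#' Spread-model parameter set
#'
#' The five calibrated quantities of the spread model: `beta`, the mean number
#' of offspring groups per pest group per step under optimal conditions;
#' `alpha1`, the scale (metres) of the natural half-Cauchy dispersal kernel;
#' `gamma`, the probability that a dispersing group in a rail cell uses
#' natural dispersal rather than the rail network; and `d_min`/`d_max`, the
#' bounds (metres) of the distance travelled along the rail network per
#' dispersal event.
#'
#' @param beta non-negative reproductive rate.
#' @param alpha1 positive kernel scale in metres.
#' @param gamma probability of natural dispersal, in \[0, 1\].
#' @param d_min,d_max network travel distance bounds in metres,
#'   `0 < d_min <= d_max`.
#' @return an object of class `slf_params`.
#' @export
slf_params <- function(beta, alpha1, gamma, d_min, d_max) {
  if (beta < 0) stop("beta must be >= 0")
  if (alpha1 <= 0) stop("alpha1 must be > 0")
  if (gamma < 0 || gamma > 1) stop("gamma must lie in [0, 1]")
  if (d_min <= 0 || d_min > d_max) stop("need 0 < d_min <= d_max")
  structure(list(beta = as.numeric(beta), alpha1 = as.numeric(alpha1),
                 gamma = as.numeric(gamma), d_min = as.numeric(d_min),
                 d_max = as.numeric(d_max)), class = "slf_params")
}

#' @export
print.slf_params <- function(x, ...) {
  cat(sprintf(
    "slf_params: beta=%.4g alpha1=%.4g m gamma=%.4g d_min=%.4g m d_max=%.4g m\n",
    x$beta, x$alpha1, x$gamma, x$d_min, x$d_max))
  invisible(x)
}

#' Per-cell infestation state
#'
#' Tracks, per cell, the integer number of pest groups and the number of
#' infested host units `I`. A cell with `I >= 1` counts as infested; with no
#' mortality or treatment in scope, infested cells never revert within a run.
#'
#' @param year calendar year of the snapshot.
#' @param groups integer matrix of pest groups per cell.
#' @param infested_hosts integer matrix of infested host units `I`; must not
#'   exceed the landscape's `host_total` cellwise.
#' @param landscape the `slf_landscape` the state lives on (used to validate
#'   `I <= N`).
#' @return an object of class `slf_state`.
#' @export
slf_state <- function(year, groups, infested_hosts, landscape = NULL) {
  groups <- as.matrix(groups); infested_hosts <- as.matrix(infested_hosts)
  if (!identical(dim(groups), dim(infested_hosts)))
    stop("groups and infested_hosts dimensions differ")
  if (any(groups < 0) || any(infested_hosts < 0)) stop("counts must be >= 0")
  if (!is.null(landscape)) {
    if (!identical(dim(groups), c(landscape$n_rows, landscape$n_cols)))
      stop("state dimensions do not match the landscape")
    if (any(infested_hosts > landscape$host_total))
      stop("infested hosts exceed total hosts in some cell")
  }
  structure(list(year = year, groups = groups, infested_hosts = infested_hosts),
            class = "slf_state")
}

#' Seed an initial infestation
#'
#' @param landscape an `slf_landscape`.
#' @param cells two-column matrix (row, col) of 1-based introduction cells, or
#'   a length-2 vector for a single cell.
#' @param year calendar year of the introduction.
#' @param groups groups placed in each introduction cell (default 1).
#' @return an `slf_state` with one infested host unit per introduction cell.
#' @export
initial_state <- function(landscape, cells, year, groups = 1L) {
  if (is.null(dim(cells))) cells <- matrix(cells, ncol = 2)
  g <- matrix(0L, landscape$n_rows, landscape$n_cols)
  inf <- matrix(0L, landscape$n_rows, landscape$n_cols)
  for (i in seq_len(nrow(cells))) {
    r <- cells[i, 1]; c <- cells[i, 2]
    if (r < 1 || r > landscape$n_rows || c < 1 || c > landscape$n_cols)
      stop("introduction cell outside the grid")
    g[r, c] <- g[r, c] + as.integer(groups)
    inf[r, c] <- min(max(1L, inf[r, c] + 1L), landscape$host_total[r, c])
  }
  slf_state(year, g, inf, landscape)
}

#' Environment-modified reproductive rate
#'
#' Composes the baseline reproductive rate with the local environment
#' multiplicatively: `beta * T * X`, where `T` is the monthly temperature
#' coefficient in \[0, 1\] and `X` the binary seasonality flag. For example, a
#' baseline rate of 2.2 under a temperature coefficient of 0.7 in season gives
#' a modified rate of 1.54, which parameterises the Poisson offspring draws.
#'
#' @param beta baseline rate, `>= 0`. Vectorised.
#' @param temp_coef temperature coefficient in \[0, 1\]. Vectorised.
#' @param season_flag 0 or 1. Vectorised.
#' @return the modified rate `beta * temp_coef * season_flag`.
#' @examples
#' modified_rate(2.2, 0.7, 1)   # 1.54
#' @export
modified_rate <- function(beta, temp_coef, season_flag = 1) {
  if (any(beta < 0)) stop("beta must be >= 0")
  if (any(temp_coef < 0 | temp_coef > 1))
    stop("temp_coef must lie in [0, 1]")
  if (!all(season_flag %in% c(0, 1))) stop("season_flag must be 0 or 1")
  beta * temp_coef * season_flag
}

#' Locate the cell containing a point
#'
#' Cells are half-open along both grid axes: a point on the boundary between
#' two cells belongs to the next cell in the direction of increasing column
#' (east) or increasing row (south). Every strictly in-bounds point therefore
#' maps to exactly one cell. Out-of-bounds points raise an error; they are
#' never clamped.
#'
#' @param x,y point coordinates in metres (vectorised).
#' @param landscape an `slf_landscape`.
#' @return a two-column integer matrix of 1-based (row, col).
#' @export
cell_of <- function(x, y, landscape) {
  cs <- landscape$cell_size
  col <- floor((x - landscape$origin[1]) / cs)
  row <- floor((landscape$origin[2] - y) / cs)
  bad <- col < 0 | col >= landscape$n_cols | row < 0 | row >= landscape$n_rows
  if (any(bad))
    stop(sprintf("point (%g, %g) lies outside the grid", x[bad][1], y[bad][1]))
  cbind(row = as.integer(row) + 1L, col = as.integer(col) + 1L)
}

# Vectorised variant that flags out-of-bounds points instead of erroring;
# used by the simulator, where dispersers crossing the boundary are lost.
cell_of_or_na <- function(x, y, landscape) {
  cs <- landscape$cell_size
  col <- floor((x - landscape$origin[1]) / cs)
  row <- floor((landscape$origin[2] - y) / cs)
  bad <- col < 0 | col >= landscape$n_cols | row < 0 | row >= landscape$n_rows
  row[bad] <- NA_integer_; col[bad] <- NA_integer_
  cbind(row = as.integer(row) + 1L, col = as.integer(col) + 1L)
}

#' Centre coordinates of cells
#'
#' @param row,col 1-based cell indices (vectorised).
#' @param landscape an `slf_landscape`.
#' @return a two-column matrix of (x, y) in metres.
#' @export
cell_center <- function(row, col, landscape) {
  cs <- landscape$cell_size
  cbind(x = landscape$origin[1] + (col - 0.5) * cs,
        y = landscape$origin[2] - (row - 0.5) * cs)
}

#' Presence/absence survey records
#'
#' @param df data frame with columns `x`, `y` (metres), `year`, and `status`
#'   (`"positive"` or `"negative"`).
#' @param landscape optional `slf_landscape`; when given, every record must
#'   fall inside the grid.
#' @return the validated data frame with class `slf_observations`.
#' @export
slf_observations <- function(df, landscape = NULL) {
  need <- c("x", "y", "year", "status")
  if (!all(need %in% names(df)))
    stop("observations need columns x, y, year, status")
  if (nrow(df) == 0L) stop("empty observation set")
  if (!all(df$status %in% c("positive", "negative")))
    stop("status must be 'positive' or 'negative'")
  if (!is.null(landscape)) cell_of(df$x, df$y, landscape)  # errors if outside
  df <- as.data.frame(df)[, need]
  class(df) <- c("slf_observations", "data.frame")
  df
}
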