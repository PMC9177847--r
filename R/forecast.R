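#' Ensemble probability-of-occurrence forecast
#'
#' Runs the stochastic spread model `n_runs` times, each run drawing a
#' parameter set (a fixed `slf_params`, or one posterior row per run so that
#' calibrated uncertainty propagates) and a weather realisation per simulated
#' year (whole historical years resampled with replacement, preserving
#' within-year month correlation). The probability of occurrence of a cell in
#' a year is the number of runs in which the cell was infested in that year
#' divided by `n_runs`.
#'
#' @param init an `slf_state` at the forecast start year.
#' @param landscape an `slf_landscape`.
#' @param weather an `slf_weather` or a list of historical `slf_weather`
#'   realisations to resample from.
#' @param params an `slf_params`, or a data frame of posterior parameter sets
#'   (columns beta, alpha1, gamma, d_min, d_max) sampled once per run.
#' @param network an `slf_network` or `NULL`.
#' @param config an `slf_sim_config` giving the forecast horizon.
#' @param n_runs ensemble size.
#' @return an object of class `slf_ensemble`: `years`, `prob` (rows x cols x
#'   years array of probabilities), `n_runs`.
#' @export
run_ensemble <- function(init, landscape, weather, params, network = NULL,
                         config, n_runs = 10000L) {
  if (n_runs < 1L) stop("n_runs must be >= 1")
  ctx <- build_sim_ctx(landscape, weather, network, config)
  n_w <- length(ctx$weather)
  years <- seq(init$year, config$end_year)
  n_sim <- length(years) - 1L
  counts <- array(0L, dim = c(landscape$n_rows, landscape$n_cols, length(years)))
  posterior <- if (is.data.frame(params)) params else NULL
  for (r in seq_len(n_runs)) {
    p <- if (is.null(posterior)) params
    else {
      row <- posterior[sample.int(nrow(posterior), 1L), ]
      slf_params(row$beta, row$alpha1, row$gamma, row$d_min, row$d_max)
    }
    ym <- if (n_w > 1L) sample.int(n_w, n_sim, replace = TRUE)
    else rep(1L, n_sim)
    run <- simulate_spread(init, landscape, weather, p, network, config,
                           year_map = ym, ctx = ctx)
    for (k in seq_along(years))
      counts[, , k] <- counts[, , k] + run$infested[[k]]
  }
  structure(list(years = years, prob = counts / n_runs, n_runs = n_runs),
            class = "slf_ensemble")
}

#' @export
print.slf_ensemble <- function(x, ...) {
  cat(sprintf("slf_ensemble: %d runs, years %d-%d\n", x$n_runs,
              min(x$years), max(x$years)))
  cat("  cells with probability > 0.5 by year:",
      paste(apply(x$prob > 0.5, 3, sum), collapse = " "), "\n")
  invisible(x)
}

#' Forecast from a calibrated model
#'
#' Ensemble forecast using the posterior sample of an [slf_calibrate()] fit:
#' each run draws one kept parameter set, so the forecast reflects parameter
#' uncertainty.
#'
#' @param object an `slf_abc`.
#' @param end_year forecast horizon (required).
#' @param n_runs ensemble size (default 10000, the headline design; desk
#'   examples use far fewer).
#' @param weather optional replacement weather (e.g. a list of historical
#'   realisations); defaults to the calibration weather.
#' @param init optional replacement starting state; by default the forecast
#'   re-runs from the calibration start state, so calibration years are
#'   re-simulated before the horizon extends beyond them.
#' @param ... unused.
#' @return an `slf_ensemble`.
#' @export
predict.slf_abc <- function(object, end_year, n_runs = 10000L, weather = NULL,
                            init = NULL, ...) {
  cfg <- object$sim_config
  cfg$end_year <- end_year
  run_ensemble(if (is.null(init)) object$init else init,
               object$landscape,
               if (is.null(weather)) object$weather else weather,
               object$posterior, object$network, cfg, n_runs = n_runs)
}

#' @export
plot.slf_ensemble <- function(x, year = max(x$years), ...) {
  k <- match(year, x$years)
  if (is.na(k)) stop("year not in the ensemble")
  graphics::image(t(x$prob[nrow(x$prob):1, , k]), zlim = c(0, 1),
                  main = sprintf("probability of occurrence, %d", year),
                  col = grDevices::hcl.colors(32, "YlOrRd", rev = TRUE), ...)
  invisible(x)
}

#' Downscale a probability raster and mask by host presence
#'
#' Replicates each coarse cell into a `factor` x `factor` block of fine cells
#' (e.g. 5 km to 1 km) and sets the probability to 0 in fine cells with no
#' host occurrence.
#'
#' @param prob coarse probability matrix.
#' @param host_fine fine-resolution host matrix (0 = host absent).
#' @param factor integer downscaling factor; fine dims must equal coarse dims
#'   times `factor`.
#' @return fine-resolution probability matrix.
#' @export
mask_and_downscale <- function(prob, host_fine, factor) {
  factor <- as.integer(factor)
  if (!identical(dim(host_fine), dim(prob) * factor))
    stop(sprintf("dimension mismatch: coarse %dx%d with factor %d vs fine %dx%d",
                 nrow(prob), ncol(prob), factor, nrow(host_fine), ncol(host_fine)))
  fine <- prob %x% matrix(1, factor, factor)
  fine[host_fine == 0] <- 0
  fine
}

#' Zonal (county) aggregation of a probability raster
#'
#' @param prob probability matrix.
#' @param zones integer/character matrix of zone labels, aligned with `prob`.
#' @param method `"mean"` or `"max"` of member-cell probabilities.
#' @param zone_ids optional vector of zones to report; zones with no member
#'   cells are reported as `NA` (flagged missing), never as 0.
#' @return data frame with columns `zone` and `value`.
#' @export
county_probability <- function(prob, zones, method = c("mean", "max"),
                               zone_ids = NULL) {
  method <- match.arg(method)
  if (!identical(dim(zones), dim(prob)))
    stop("zone raster not aligned with probability raster")
  f <- if (method == "mean") mean else max
  agg <- tapply(as.vector(prob), as.vector(zones), f)
  if (is.null(zone_ids)) zone_ids <- sort(names(agg))
  value <- agg[match(as.character(zone_ids), names(agg))]
  data.frame(zone = zone_ids, value = as.numeric(value), row.names = NULL)
}

#' Risk categories and their boundaries
#'
#' The categorisation schema used for map comparison: probabilities below
#' 8.359% are unsuitable, from 8.359% up to 26.89% low risk, from 26.89% up
#' to 51.99% medium risk, and 51.99% or above high risk. Values exactly at a
#' boundary belong to the higher category ("below" is strict).
#'
#' @return named numeric vector of the three boundaries (as probabilities).
#' @export
risk_thresholds <- function() {
  c(low = 0.08359, medium = 0.2689, high = 0.5199)
}

#' @rdname risk_thresholds
#' @param prob probabilities in \[0, 1\] (vector or matrix; dimensions are
#'   preserved).
#' @return for `categorize`: a character vector/matrix with values
#'   `"unsuitable"`, `"low"`, `"medium"`, `"high"`.
#' @export
categorize <- function(prob) {
  if (any(prob < 0 | prob > 1, na.rm = TRUE))
    stop("probabilities must lie in [0, 1]")
  th <- unname(risk_thresholds())
  out <- ifelse(prob < th[1], "unsuitable",
         ifelse(prob < th[2], "low",
         ifelse(prob < th[3], "medium", "high")))
  names(out) <- NULL
  dim(out) <- dim(prob)
  out
}

risk_levels <- c("unsuitable", "low", "medium", "high")

#' Compare two categorised risk maps
#'
#' Cross-tabulates the category pairs of two aligned maps as pixel fractions
#' and summarises agreement: the fraction where both maps say unsuitable
#' (both absent), where both predict some presence, and the one-sided
#' disagreements with a per-category breakdown of the disagreeing map.
#'
#' @param map_a,map_b aligned category matrices/vectors (values among
#'   unsuitable/low/medium/high, e.g. from [categorize()]).
#' @return an object of class `slf_map_comparison`: `table` (4x4 fraction
#'   cross-tabulation, rows = map_a), `counts`, and `summary` (both_absent,
#'   both_present, a_only, b_only with breakdowns).
#' @export
compare_maps <- function(map_a, map_b) {
  if (!identical(dim(map_a), dim(map_b)) || length(map_a) != length(map_b))
    stop("maps are not aligned")
  a <- factor(as.vector(map_a), levels = risk_levels)
  b <- factor(as.vector(map_b), levels = risk_levels)
  if (anyNA(a) || anyNA(b)) stop("unknown risk category in input")
  counts <- table(a = a, b = b)
  frac <- counts / length(a)
  a_pres <- a != "unsuitable"; b_pres <- b != "unsuitable"
  a_only <- a_pres & !b_pres; b_only <- b_pres & !a_pres
  brk <- function(f, side) {
    if (!any(f)) return(stats::setNames(numeric(3), risk_levels[-1]))
    prop.table(table(factor(as.vector(side)[f], levels = risk_levels[-1])))
  }
  structure(list(
    table = frac, counts = counts,
    summary = list(
      both_absent = mean(!a_pres & !b_pres),
      both_present = mean(a_pres & b_pres),
      a_only = mean(a_only), b_only = mean(b_only),
      a_only_by_category = brk(a_only, a),
      b_only_by_category = brk(b_only, b))),
    class = "slf_map_comparison")
}

#' @export
print.slf_map_comparison <- function(x, ...) {
  s <- x$summary
  cat(sprintf("both absent %.1f%% | both present %.1f%% | a only %.1f%% | b only %.1f%%\n",
              100 * s$both_absent, 100 * s$both_present, 100 * s$a_only,
              100 * s$b_only))
  print(round(x$table, 4))
  invisible(x)
}
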