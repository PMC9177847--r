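#' Prior bounds for the spread parameters
#'
#' The first ABC generation draws each parameter independently from a uniform
#' distribution over these bounds; later generations reject multivariate
#' normal proposals that fall outside them (or violate `d_min <= d_max`). The
#' defaults are working assumptions spanning the plausible range at a 5-km
#' grid: a reproductive rate up to a few offspring groups per group per step,
#' a natural-kernel scale up to about one to two cell widths, mostly-natural
#' dispersal, and rail rides of tens to hundreds of kilometres.
#'
#' @param beta,alpha1,gamma,d_min,d_max length-2 numeric `c(lower, upper)`.
#' @return a named list of bounds.
#' @export
prior_bounds <- function(beta = c(0.2, 5), alpha1 = c(500, 8000),
                         gamma = c(0.5, 1), d_min = c(5e3, 5e4),
                         d_max = c(5e4, 3e5)) {
  b <- list(beta = beta, alpha1 = alpha1, gamma = gamma,
            d_min = d_min, d_max = d_max)
  for (nm in names(b))
    if (length(b[[nm]]) != 2L || b[[nm]][1] > b[[nm]][2])
      stop("each bound must be c(lower, upper)")
  b
}

#' ABC-SMC calibration settings
#'
#' Defaults follow the headline calibration design: 10,000 parameter sets
#' kept per generation, all four accuracy statistics strictly above 0.65 to
#' keep a set in the first generation, seven generations, with each later
#' generation's thresholds set to the means of the previous generation's kept
#' statistics and its proposal a multivariate normal fitted to the kept sets.
#' Desk-scale experiments override `quota` and `generations`.
#'
#' @param quota kept parameter sets per generation.
#' @param generations number of SMC generations.
#' @param initial_thresholds scalar or length-4 vector (accuracy, precision,
#'   recall, specificity) applied in generation 1; "above" is strict.
#' @param bounds see [prior_bounds()].
#' @param replicates simulations per drawn parameter set; statistics are
#'   averaged over replicates before gating.
#' @param max_draw_factor abort a generation after `max_draw_factor * quota`
#'   draws (an acceptance-rate floor of `1/max_draw_factor`).
#' @return an object of class `slf_abc_config`.
#' @export
slf_abc_config <- function(quota = 10000L, generations = 7L,
                           initial_thresholds = 0.65, bounds = prior_bounds(),
                           replicates = 1L, max_draw_factor = 200L) {
  if (quota < 1L) stop("quota must be >= 1")
  if (generations < 1L) stop("generations must be >= 1")
  th <- rep_len(initial_thresholds, 4L)
  if (any(th < 0 | th > 1)) stop("thresholds must lie in [0, 1]")
  names(th) <- c("accuracy", "precision", "recall", "specificity")
  structure(list(quota = as.integer(quota), generations = as.integer(generations),
                 initial_thresholds = th, bounds = bounds,
                 replicates = as.integer(replicates),
                 max_draw_factor = as.integer(max_draw_factor)),
            class = "slf_abc_config")
}

param_names <- c("beta", "alpha1", "gamma", "d_min", "d_max")
stat_names <- c("accuracy", "precision", "recall", "specificity")

draw_params <- function(proposal, bounds) {
  if (proposal$type == "uniform") {
    p <- vapply(param_names, function(nm)
      stats::runif(1, bounds[[nm]][1], bounds[[nm]][2]), 0)
    if (p["d_min"] > p["d_max"]) return(NULL)
    return(p)
  }
  p <- as.vector(MASS::mvrnorm(1, proposal$mean, proposal$cov))
  names(p) <- param_names
  for (nm in param_names)
    if (p[nm] < bounds[[nm]][1] || p[nm] > bounds[[nm]][2]) return(NULL)
  if (p["d_min"] > p["d_max"]) return(NULL)
  p
}

#' Run one ABC-SMC generation
#'
#' Draws parameter sets (generation 1: independent uniforms over the bounds;
#' later: a multivariate normal fitted to the previous generation's kept
#' sets, with out-of-bounds draws rejected), simulates each, scores the run
#' against the surveys, and keeps sets whose four accuracy statistics all
#' strictly exceed the generation's thresholds, until the quota is met.
#'
#' @param proposal either `list(type = "uniform")` or
#'   `list(type = "mvn", mean =, cov =)`.
#' @param simulator function taking a named parameter vector and returning
#'   either an `slf_run` (scored against `observations`) or an
#'   `slf_accuracy` directly (useful for deterministic stubs in testing).
#' @param observations an `slf_observations` (may be `NULL` when the
#'   simulator returns statistics directly).
#' @param landscape the `slf_landscape` for survey-to-cell matching.
#' @param thresholds named length-4 vector of acceptance thresholds.
#' @param config an `slf_abc_config` (quota, bounds, replicates, draw cap).
#' @param index generation number (bookkeeping only).
#' @return an object of class `slf_generation`: `kept` (data frame of
#'   parameters + statistics), `thresholds` used, `next_thresholds`
#'   (componentwise means of kept statistics), `proposal_mean` /
#'   `proposal_cov` fitted to the kept sets, and the draw/acceptance counts.
#' @export
run_generation <- function(proposal, simulator, observations, landscape,
                           thresholds, config, index = 1L) {
  kept <- matrix(NA_real_, config$quota, 9L,
                 dimnames = list(NULL, c(param_names, stat_names)))
  n_kept <- 0L; n_draws <- 0L
  max_draws <- config$max_draw_factor * config$quota
  while (n_kept < config$quota) {
    if (n_draws >= max_draws)
      stop(sprintf(
        "generation %d: acceptance rate %.4f below floor 1/%d after %d draws",
        index, n_kept / n_draws, config$max_draw_factor, n_draws))
    p <- draw_params(proposal, config$bounds)
    n_draws <- n_draws + 1L
    if (is.null(p)) next
    st <- matrix(NA_real_, config$replicates, 4L)
    for (r in seq_len(config$replicates)) {
      res <- simulator(p)
      if (!inherits(res, "slf_accuracy"))
        res <- score_run(res, observations, landscape)
      st[r, ] <- c(res$accuracy, res$precision, res$recall, res$specificity)
    }
    s <- colMeans(st)
    if (anyNA(s) || !all(s > thresholds)) next
    n_kept <- n_kept + 1L
    kept[n_kept, ] <- c(p, s)
  }
  kept <- as.data.frame(kept)
  stats_kept <- as.matrix(kept[, stat_names])
  pm <- colMeans(as.matrix(kept[, param_names]))
  pc <- stats::cov(as.matrix(kept[, param_names]))
  structure(list(index = index, kept = kept, thresholds = thresholds,
                 next_thresholds = colMeans(stats_kept),
                 proposal_mean = pm, proposal_cov = pc,
                 n_draws = n_draws, acceptance_rate = config$quota / n_draws),
            class = "slf_generation")
}

#' Calibrate the spread model with ABC sequential Monte Carlo
#'
#' The fitting function of the package. Chains [run_generation()] for
#' `config$generations` generations: generation 1 draws from the uniform
#' prior and gates on `initial_thresholds`; each subsequent generation draws
#' from a multivariate normal fitted to the previous kept sets and gates on
#' the means of the previous kept statistics (so thresholds tighten across
#' generations). The final generation's kept sets are the posterior sample.
#'
#' @param observations an `slf_observations` of presence/absence surveys.
#' @param landscape an `slf_landscape`.
#' @param weather an `slf_weather`.
#' @param init an `slf_state` at the introduction year.
#' @param network an `slf_network` or `NULL`.
#' @param sim_config an `slf_sim_config` covering the survey years.
#' @param config an `slf_abc_config`.
#' @param simulator optional override of the run simulator (see
#'   [run_generation()]); by default runs [simulate_spread()] on the inputs.
#' @return an object of class `slf_abc`: `posterior` (data frame of the final
#'   generation's kept parameter sets and their statistics), `generations`
#'   (per-generation provenance), the configs, and the model inputs (kept for
#'   [predict.slf_abc()] and [simulate.slf_abc()]).
#' @examples
#' \donttest{
#' sc <- gen_scenario(scenario_spec(n_rows = 20, n_cols = 20, seed = 1))
#' fit <- slf_calibrate(sc$surveys, sc$landscape, sc$weather, sc$init,
#'                      sc$network, sc$sim_config,
#'                      slf_abc_config(quota = 50, generations = 2,
#'                                     initial_thresholds = 0.5))
#' coef(fit)
#' }
#' @export
slf_calibrate <- function(observations, landscape, weather, init,
                          network = NULL, sim_config,
                          config = slf_abc_config(), simulator = NULL) {
  cl <- match.call()
  if (is.null(simulator)) {
    ctx <- build_sim_ctx(landscape, weather, network, sim_config)
    # observation cells/years resolved once; per-draw scoring is then a
    # handful of vectorised lookups
    rc <- cell_of(observations$x, observations$y, landscape)
    obs_lin <- (rc[, 2] - 1L) * landscape$n_rows + rc[, 1]
    obs_pos <- observations$status == "positive"
    by_year <- split(seq_len(nrow(observations)), observations$year)
    if (!all(unique(observations$year) %in% seq(init$year, sim_config$end_year)))
      stop("observation years outside the simulated span")
    simulator <- function(p) {
      run <- simulate_spread(init, landscape, weather,
                             slf_params(p[["beta"]], p[["alpha1"]], p[["gamma"]],
                                        p[["d_min"]], p[["d_max"]]),
                             network, sim_config, ctx = ctx)
      sim_pos <- logical(nrow(observations))
      for (y in names(by_year)) {
        i <- by_year[[y]]
        sim_pos[i] <- run$infested[[y]][obs_lin[i]]
      }
      accuracy_stats(tp = sum(obs_pos & sim_pos), fp = sum(!obs_pos & sim_pos),
                     fn = sum(obs_pos & !sim_pos), tn = sum(!obs_pos & !sim_pos))
    }
  }
  gens <- vector("list", config$generations)
  proposal <- list(type = "uniform")
  thresholds <- config$initial_thresholds
  for (g in seq_len(config$generations)) {
    gens[[g]] <- run_generation(proposal, simulator, observations, landscape,
                                thresholds, config, index = g)
    proposal <- list(type = "mvn", mean = gens[[g]]$proposal_mean,
                     cov = gens[[g]]$proposal_cov)
    thresholds <- gens[[g]]$next_thresholds
  }
  structure(list(posterior = gens[[config$generations]]$kept,
                 generations = gens, config = config, sim_config = sim_config,
                 landscape = landscape, weather = weather, init = init,
                 network = network, call = cl),
            class = "slf_abc")
}

#' @export
print.slf_abc <- function(x, ...) {
  cat("ABC-SMC calibrated spread model\n")
  cat(sprintf("  %d generation(s), %d kept sets per generation\n",
              length(x$generations), x$config$quota))
  cat("  posterior means:\n")
  print(round(coef(x), 4))
  invisible(x)
}

#' @export
coef.slf_abc <- function(object, ...) {
  colMeans(as.matrix(object$posterior[, param_names]))
}

#' @export
summary.slf_abc <- function(object, ...) {
  post <- as.matrix(object$posterior[, param_names])
  qs <- t(apply(post, 2, stats::quantile, c(0.05, 0.5, 0.95)))
  tab <- cbind(mean = colMeans(post), sd = apply(post, 2, stats::sd), qs)
  thr <- t(vapply(object$generations, `[[`, numeric(4), "thresholds"))
  acc <- vapply(object$generations, `[[`, 0, "acceptance_rate")
  out <- list(posterior = tab, thresholds = thr, acceptance_rates = acc,
              n_kept = nrow(object$posterior))
  class(out) <- "summary.slf_abc"
  out
}

#' @export
print.summary.slf_abc <- function(x, ...) {
  cat("Posterior sample of", x$n_kept, "parameter sets\n")
  print(round(x$posterior, 4))
  cat("\nAcceptance thresholds by generation:\n")
  print(round(x$thresholds, 4))
  cat("\nAcceptance rates:", paste(round(x$acceptance_rates, 3), collapse = " "), "\n")
  invisible(x)
}

#' @export
plot.slf_abc <- function(x, truth = NULL, ...) {
  op <- graphics::par(mfrow = c(2, 3), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  for (nm in param_names) {
    graphics::hist(x$posterior[[nm]], main = nm, xlab = nm,
                   col = "grey80", border = "white", breaks = 20)
    if (!is.null(truth)) graphics::abline(v = truth[[nm]], col = "red", lwd = 2)
  }
  invisible(x)
}

#' Simulate spread trajectories from a calibrated model
#'
#' Each simulation draws one parameter set from the posterior sample (or uses
#' the posterior mean) and re-runs the stochastic spread model on the stored
#' inputs.
#'
#' @param object an `slf_abc`.
#' @param nsim number of trajectories.
#' @param seed optional RNG seed.
#' @param use one of `"draw"` (sample posterior rows) or `"mean"`.
#' @param end_year final simulated year; defaults to the calibration span.
#' @param ... unused.
#' @return a list of `slf_run` objects.
#' @export
simulate.slf_abc <- function(object, nsim = 1, seed = NULL,
                             use = c("draw", "mean"), end_year = NULL, ...) {
  use <- match.arg(use)
  if (!is.null(seed)) set.seed(seed)
  cfg <- object$sim_config
  if (!is.null(end_year)) cfg$end_year <- end_year
  ctx <- build_sim_ctx(object$landscape, object$weather, object$network, cfg)
  lapply(seq_len(nsim), function(i) {
    p <- if (use == "mean") coef(object)
    else unlist(object$posterior[sample.int(nrow(object$posterior), 1L),
                                 param_names])
    simulate_spread(object$init, object$landscape, object$weather,
                    slf_params(p["beta"], p["alpha1"], p["gamma"],
                               p["d_min"], p["d_max"]),
                    object$network, cfg, ctx = ctx)
  })
}
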