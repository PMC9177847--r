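#' Read and write ESRI ASCII grid rasters
#'
#' The plain-text single-band raster format used throughout the package:
#' a six-line header (ncols, nrows, xllcorner, yllcorner, cellsize,
#' NODATA_value) followed by rows from north to south. Values are written
#' with full double precision so that write-then-read is the identity.
#' NODATA cells are mapped to 0 on read (hosts absent / coefficient 0) and
#' the count of such cells is reported.
#'
#' @param path file path.
#' @return for `read_ascii_grid`: a list with `values` (matrix), `cell_size`,
#'   `origin` (upper-left x, y), and `n_nodata`.
#' @export
read_ascii_grid <- function(path) {
  if (!file.exists(path)) stop("no such raster: ", path)
  lines <- readLines(path, n = 6L)
  hdr <- list()
  for (ln in lines) {
    kv <- strsplit(trimws(ln), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr))) stop("malformed ASCII grid header: ", path)
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  vals <- scan(path, skip = 6L, quiet = TRUE)
  if (length(vals) != hdr$ncols * hdr$nrows)
    stop("ASCII grid value count does not match header dims: ", path)
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  nd <- m == nodata
  m[nd] <- 0
  list(values = m, cell_size = hdr$cellsize,
       origin = c(hdr$xllcorner, hdr$yllcorner + hdr$nrows * hdr$cellsize),
       n_nodata = sum(nd))
}

#' @rdname read_ascii_grid
#' @param values numeric matrix (row 1 = northernmost).
#' @param cell_size cell edge in metres.
#' @param origin upper-left (x, y) in metres.
#' @param nodata value standing for missing cells on disk.
#' @export
write_ascii_grid <- function(values, path, cell_size, origin = c(0, 0),
                             nodata = -9999) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(
    paste("ncols", ncol(values)), paste("nrows", nrow(values)),
    paste("xllcorner", sprintf("%.17g", origin[1])),
    paste("yllcorner", sprintf("%.17g", origin[2] - nrow(values) * cell_size)),
    paste("cellsize", sprintf("%.17g", cell_size)),
    paste("NODATA_value", nodata)), con)
  writeLines(apply(values, 1, function(r)
    paste(sprintf("%.17g", r), collapse = " ")), con)
  invisible(path)
}

# Two grids must share one session geometry; report both when they differ.
check_geometry <- function(a, b, what = "raster") {
  if (!isTRUE(all.equal(a$cell_size, b$cell_size)) ||
      !isTRUE(all.equal(a$origin, b$origin)) ||
      !identical(dim(a$values), dim(b$values)))
    stop(sprintf(
      "%s geometry mismatch:\n  first: %dx%d cell %g origin (%g, %g)\n  second: %dx%d cell %g origin (%g, %g)",
      what, nrow(a$values), ncol(a$values), a$cell_size, a$origin[1], a$origin[2],
      nrow(b$values), ncol(b$values), b$cell_size, b$origin[1], b$origin[2]))
  invisible(TRUE)
}

#' Read/write survey observations as CSV
#'
#' @param path CSV path with columns x, y, year, status.
#' @param landscape optional landscape for bounds validation.
#' @return an `slf_observations`.
#' @export
read_observations <- function(path, landscape = NULL) {
  slf_observations(utils::read.csv(path), landscape)
}

#' @rdname read_observations
#' @param observations an `slf_observations`.
#' @export
write_observations <- function(observations, path) {
  df <- as.data.frame(observations)
  # full double precision so the bundle round-trips losslessly
  df$x <- sprintf("%.17g", df$x)
  df$y <- sprintf("%.17g", df$y)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

parse_wkt_linestring <- function(wkt) {
  body <- sub("^\\s*LINESTRING\\s*\\(", "", wkt)
  if (identical(body, wkt)) stop("not a WKT LINESTRING: ", wkt)
  body <- sub("\\)\\s*$", "", body)
  pts <- strsplit(strsplit(body, ",")[[1]], "\\s+")
  v <- t(vapply(pts, function(p) as.numeric(p[p != ""]), numeric(2)))
  unname(v)
}

format_wkt_linestring <- function(verts) {
  sprintf("LINESTRING (%s)", paste(
    sprintf("%.17g %.17g", verts[, 1], verts[, 2]), collapse = ", "))
}

#' Read/write a rail network as node and edge CSV files
#'
#' Nodes: columns `id`, `x`, `y`. Edges: columns `id`, `node_a`, `node_b`,
#' `wkt` (a WKT LINESTRING from node_a to node_b). The loader validates the
#' network invariants (endpoints declared, polylines anchored at their
#' nodes).
#'
#' @param nodes_path,edges_path CSV paths.
#' @return an `slf_network`.
#' @export
read_network <- function(nodes_path, edges_path) {
  nodes <- utils::read.csv(nodes_path, colClasses = c(id = "character"))
  ed <- utils::read.csv(edges_path, colClasses = c(
    id = "character", node_a = "character", node_b = "character"))
  edges <- lapply(seq_len(nrow(ed)), function(i)
    list(id = ed$id[i], node_a = ed$node_a[i], node_b = ed$node_b[i],
         verts = parse_wkt_linestring(ed$wkt[i])))
  slf_network(nodes, edges)
}

#' @rdname read_network
#' @param network an `slf_network`.
#' @export
write_network <- function(network, nodes_path, edges_path) {
  nd <- network$nodes
  nd$x <- sprintf("%.17g", nd$x); nd$y <- sprintf("%.17g", nd$y)
  utils::write.csv(nd, nodes_path, row.names = FALSE)
  ed <- data.frame(
    id = vapply(network$edges, `[[`, "", "id"),
    node_a = vapply(network$edges, `[[`, "", "node_a"),
    node_b = vapply(network$edges, `[[`, "", "node_b"),
    wkt = vapply(network$edges, function(e) format_wkt_linestring(e$verts), ""))
  utils::write.csv(ed, edges_path, row.names = FALSE)
  invisible(edges_path)
}

#' Write a synthetic scenario bundle to a directory
#'
#' Writes the landscape, the 12 monthly weather grids, the network CSVs, the
#' surveys, the per-year true infestation grids, and a JSON manifest holding
#' the scenario spec, the true parameters, and the seed — so ground truth is
#' always recoverable from the bundle for recovery experiments.
#'
#' @param scenario an `slf_scenario`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(scenario, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  L <- scenario$landscape
  write_ascii_grid(L$host_total, file.path(dir, "host_total.asc"),
                   L$cell_size, L$origin)
  for (m in 1:12)
    write_ascii_grid(scenario$weather$coefficients[, , m],
                     file.path(dir, sprintf("weather_%02d.asc", m)),
                     L$cell_size, L$origin)
  write_network(scenario$network, file.path(dir, "nodes.csv"),
                file.path(dir, "edges.csv"))
  write_observations(scenario$surveys, file.path(dir, "surveys.csv"))
  for (y in scenario$true_run$years)
    write_ascii_grid(scenario$true_run$infested[[as.character(y)]] * 1L,
                     file.path(dir, sprintf("true_infested_%d.asc", y)),
                     L$cell_size, L$origin)
  spec <- scenario$spec
  spec$true_params <- unclass(spec$true_params)
  manifest <- list(
    spec = spec[setdiff(names(spec), "")],
    season_mask = scenario$weather$season_mask,
    intro = list(cell = which_intro(scenario$init), year = scenario$init$year,
                 groups = scenario$spec$intro_groups),
    sim_config = unclass(scenario$sim_config),
    package_version = as.character(utils::packageVersion("slfspread")))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

which_intro <- function(init) {
  w <- which(init$groups > 0, arr.ind = TRUE)
  as.integer(w[1, ])
}

#' @rdname write_bundle
#' @return for `read_bundle`: an `slf_scenario` reconstructed from disk
#'   (the true run is restored as per-year infested indicators).
#' @export
read_bundle <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  host <- read_ascii_grid(file.path(dir, "host_total.asc"))
  landscape <- slf_landscape(host$values, cell_size = host$cell_size,
                             origin = host$origin)
  co <- array(0, dim = c(landscape$n_rows, landscape$n_cols, 12))
  for (m in 1:12) {
    g <- read_ascii_grid(file.path(dir, sprintf("weather_%02d.asc", m)))
    check_geometry(host, g, "weather")
    co[, , m] <- g$values
  }
  weather <- slf_weather(co, manifest$season_mask)
  network <- read_network(file.path(dir, "nodes.csv"),
                          file.path(dir, "edges.csv"))
  surveys <- read_observations(file.path(dir, "surveys.csv"), landscape)
  sp <- manifest$spec
  tp <- sp$true_params
  true_params <- slf_params(tp$beta, tp$alpha1, tp$gamma, tp$d_min, tp$d_max)
  init <- initial_state(landscape, unlist(manifest$intro$cell),
                        manifest$intro$year, manifest$intro$groups)
  sim_config <- slf_sim_config(manifest$sim_config$end_year,
                               manifest$sim_config$sub_steps,
                               manifest$sim_config$apply_T_at_reproduction,
                               manifest$sim_config$apply_T_at_establishment)
  years <- seq(manifest$intro$year, sim_config$end_year)
  infested <- lapply(years, function(y)
    read_ascii_grid(file.path(dir, sprintf("true_infested_%d.asc", y)))$values >= 1)
  names(infested) <- as.character(years)
  true_run <- structure(list(states = NULL, infested = infested,
                             years = years, params = true_params,
                             config = sim_config), class = "slf_run")
  structure(list(spec = sp, landscape = landscape, weather = weather,
                 network = network, init = init, sim_config = sim_config,
                 true_params = true_params, true_run = true_run,
                 surveys = surveys),
            class = "slf_scenario")
}

#' Default run configuration
#'
#' All headline design constants under named keys: calibration quota 10,000,
#' seven generations, initial thresholds 0.65, forecast ensemble of 10,000
#' runs, 5-km resolution. `desk_profile()` is the scaled-down counterpart
#' used in examples and tests. Configurations round-trip through YAML.
#'
#' @return a nested named list.
#' @export
default_run_config <- function() {
  list(seed = 1L,
       simulation = list(cell_size = 5000, sub_steps = 12L,
                         apply_T_at_reproduction = TRUE,
                         apply_T_at_establishment = TRUE),
       calibration = list(quota = 10000L, generations = 7L,
                          initial_thresholds = 0.65,
                          bounds = prior_bounds(), replicates = 1L),
       forecast = list(n_runs = 10000L))
}

#' @rdname default_run_config
#' @export
desk_profile <- function() {
  cfg <- default_run_config()
  cfg$simulation$sub_steps <- 1L
  cfg$calibration$quota <- 200L
  cfg$calibration$generations <- 3L
  cfg$calibration$initial_thresholds <- 0.5
  cfg$forecast$n_runs <- 200L
  cfg
}

#' @rdname default_run_config
#' @param path YAML file path.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("no such config: ", path)
  yaml::read_yaml(path)
}

#' @rdname default_run_config
#' @param config a run-configuration list.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}
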