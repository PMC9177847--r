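#' Choose dispersal routes
#'
#' Each dispersing group in a cell containing a rail line takes the natural
#' kernel with probability `gamma` and the rail network otherwise
#' (Bernoulli route choice). Groups in cells with no rail always disperse
#' naturally.
#'
#' @param gamma probability of natural dispersal, in \[0, 1\].
#' @param cell_has_rail logical, recycled against `n`.
#' @param n number of draws.
#' @return character vector of `"natural"` / `"network"`.
#' @export
choose_route <- function(gamma, cell_has_rail, n = length(cell_has_rail)) {
  if (gamma < 0 || gamma > 1) stop("gamma must lie in [0, 1]")
  cell_has_rail <- rep_len(cell_has_rail, n)
  natural <- !cell_has_rail | stats::runif(n) < gamma
  ifelse(natural, "natural", "network")
}

#' Sample destinations from the natural half-Cauchy kernel
#'
#' The travelled distance is the absolute value of a Cauchy(0, `alpha1`) draw
#' (a half-Cauchy, median `alpha1`); the bearing is uniform on \[0, 360)
#' degrees with 0 = North and angles increasing clockwise, so a bearing of 0
#' displaces the source northward (+y).
#'
#' @param x,y source coordinates in metres (scalars or vectors recycled
#'   against `n`).
#' @param alpha1 kernel scale in metres, `> 0`.
#' @param n number of draws.
#' @return data frame with destination `x`, `y`, travelled `distance`, and
#'   `bearing` in degrees.
#' @export
sample_natural <- function(x, y, alpha1, n = 1L) {
  if (alpha1 <= 0) stop("alpha1 must be > 0")
  d <- abs(stats::rcauchy(n, 0, alpha1))
  bearing <- stats::runif(n, 0, 360)
  rad <- bearing * pi / 180
  data.frame(x = x + d * sin(rad), y = y + d * cos(rad),
             distance = d, bearing = bearing)
}

#' Travel along the rail network and disembark mid-edge
#'
#' A boarding group draws a travel distance from Uniform(`d_min`, `d_max`)
#' and picks an initial direction uniformly: one of the two arc directions
#' for a mid-edge start, or one of the node's incident edges when the start
#' lies exactly on a node (so a group at a junction of three arms is equally
#' likely to ride each arm). At each node passed it continues on an edge
#' chosen uniformly among the incident edges other than the one it arrived
#' on (no immediate U-turn); if the node is a dead end it disembarks there.
#' Otherwise it disembarks exactly at the residual arc-length along the
#' final edge — mid-edge disembarkation, not node-to-node hopping.
#'
#' @param network an `slf_network`.
#' @param edge 1-based index of the boarding edge.
#' @param arc_pos boarding position along the edge, metres in
#'   \[0, edge length\].
#' @param d_min,d_max travel distance bounds in metres, `0 < d_min <= d_max`.
#' @return list with destination `x`, `y` and `distance` actually travelled
#'   (less than the drawn distance only when a dead end stopped the ride).
#' @export
sample_network <- function(network, edge, arc_pos, d_min, d_max) {
  if (d_min <= 0 || d_min > d_max) stop("need 0 < d_min <= d_max")
  if (edge < 1 || edge > length(network$edges)) stop("start not on any edge")
  e <- network$edges[[edge]]
  if (arc_pos < 0 || arc_pos > e$length) stop("start not on any edge")
  drawn <- stats::runif(1, d_min, d_max)
  remaining <- drawn
  ei <- edge; pos <- arc_pos
  if (pos <= 0 || pos >= e$length) {
    # node start: ride a uniformly chosen incident edge away from the node
    node <- if (pos <= 0) e$node_a else e$node_b
    inc <- network$adjacency[[node]]
    ei <- if (length(inc) == 1L) inc else inc[sample.int(length(inc), 1L)]
    en <- network$edges[[ei]]
    if (en$node_a == node) { pos <- 0; dir <- 1 }
    else { pos <- en$length; dir <- -1 }
  } else {
    dir <- if (stats::runif(1) < 0.5) 1 else -1
  }
  repeat {
    e <- network$edges[[ei]]
    to_end <- if (dir > 0) e$length - pos else pos
    if (remaining <= to_end) {
      p <- point_at(network, ei, pos + dir * remaining)
      return(list(x = p[1], y = p[2], distance = drawn))
    }
    remaining <- remaining - to_end
    node <- if (dir > 0) e$node_b else e$node_a
    nxt <- setdiff(network$adjacency[[node]], ei)
    if (length(nxt) == 0L) {   # dead end: disembark at the node
      p <- point_at(network, ei, if (dir > 0) e$length else 0)
      return(list(x = p[1], y = p[2], distance = drawn - remaining))
    }
    ei <- if (length(nxt) == 1L) nxt else nxt[sample.int(length(nxt), 1L)]
    en <- network$edges[[ei]]
    if (en$node_a == node) { pos <- 0; dir <- 1 }
    else { pos <- en$length; dir <- -1 }
  }
}
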