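#' Railway network for network dispersal
#'
#' A rail network is a graph of nodes (projected metre coordinates) and edges,
#' each edge carrying a polyline geometry. Unlike node-to-node network models,
#' dispersers here travel an arc-length distance along the graph and can
#' disembark at any point along an edge, so edges keep their full geometry and
#' positions on the network are addressed as (edge, arc-length).
#'
#' @param nodes data frame with columns `id`, `x`, `y`.
#' @param edges list of edges, each a list with elements `id`, `node_a`,
#'   `node_b`, and `verts` (an n x 2 matrix of polyline vertices running from
#'   `node_a` to `node_b`).
#' @return an object of class `slf_network` with per-edge arc lengths and a
#'   node adjacency table.
#' @export
slf_network <- function(nodes, edges) {
  nodes <- as.data.frame(nodes)
  if (!all(c("id", "x", "y") %in% names(nodes)))
    stop("nodes need columns id, x, y")
  nodes$id <- as.character(nodes$id)
  if (anyDuplicated(nodes$id)) stop("duplicate node ids")
  node_xy <- function(id) {
    i <- match(id, nodes$id)
    if (is.na(i)) stop(sprintf("edge endpoint '%s' is not a declared node", id))
    c(nodes$x[i], nodes$y[i])
  }
  tol <- 1e-6
  edges <- lapply(edges, function(e) {
    v <- unname(as.matrix(e$verts))
    dimnames(v) <- NULL
    if (nrow(v) < 2L) stop("edge polyline needs at least two vertices")
    a <- node_xy(as.character(e$node_a)); b <- node_xy(as.character(e$node_b))
    if (max(abs(v[1, ] - a)) > tol || max(abs(v[nrow(v), ] - b)) > tol)
      stop(sprintf("edge '%s' polyline does not start/end at its nodes", e$id))
    seg <- sqrt(rowSums((v[-1, , drop = FALSE] - v[-nrow(v), , drop = FALSE])^2))
    if (any(seg <= 0)) stop("degenerate zero-length polyline segment")
    cum <- c(0, cumsum(seg))
    if (!is.null(e$length) && abs(e$length - cum[length(cum)]) > 1e-3)
      stop(sprintf("edge '%s' declared length %g differs from arc length %g",
                   e$id, e$length, cum[length(cum)]))
    list(id = as.character(e$id), node_a = as.character(e$node_a),
         node_b = as.character(e$node_b), verts = v,
         cum = cum, length = cum[length(cum)])
  })
  ids <- vapply(edges, `[[`, "", "id")
  if (anyDuplicated(ids)) stop("duplicate edge ids")
  adj <- lapply(nodes$id, function(nid)
    which(vapply(edges, function(e) e$node_a == nid || e$node_b == nid, TRUE)))
  names(adj) <- nodes$id
  structure(list(nodes = nodes, edges = edges, adjacency = adj),
            class = "slf_network")
}

#' @export
print.slf_network <- function(x, ...) {
  cat(sprintf("slf_network: %d nodes, %d edges, total length %.1f km\n",
              nrow(x$nodes), length(x$edges),
              sum(vapply(x$edges, `[[`, 0, "length")) / 1000))
  invisible(x)
}

# Point at arc-length `pos` along edge `ei` (1-based edge index).
point_at <- function(network, ei, pos) {
  e <- network$edges[[ei]]
  pos <- min(max(pos, 0), e$length)
  i <- findInterval(pos, e$cum, rightmost.closed = TRUE)
  i <- min(i, nrow(e$verts) - 1L)
  seg <- e$verts[i + 1L, ] - e$verts[i, ]
  slen <- e$cum[i + 1L] - e$cum[i]
  e$verts[i, ] + (pos - e$cum[i]) / slen * seg
}

# Cells (1-based row, col) traversed by the segment a -> b, by exact
# parametric traversal of the grid lines the segment crosses.
segment_cells <- function(a, b, landscape) {
  cs <- landscape$cell_size; ox <- landscape$origin[1]; oy <- landscape$origin[2]
  ts <- c(0, 1)
  for (d in 1:2) {
    lo <- min(a[d], b[d]); hi <- max(a[d], b[d])
    if (hi > lo) {
      if (d == 1) ks <- seq(ceiling((lo - ox) / cs), floor((hi - ox) / cs))
      else ks <- seq(ceiling((oy - hi) / cs), floor((oy - lo) / cs))
      if (length(ks)) {
        bounds <- if (d == 1) ox + ks * cs else oy - ks * cs
        ts <- c(ts, (bounds - a[d]) / (b[d] - a[d]))
      }
    }
  }
  ts <- sort(unique(pmin(pmax(ts, 0), 1)))
  mid <- (ts[-1] + ts[-length(ts)]) / 2
  if (!length(mid)) mid <- 0.5
  px <- a[1] + mid * (b[1] - a[1]); py <- a[2] + mid * (b[2] - a[2])
  rc <- cell_of_or_na(px, py, landscape)
  rc[!is.na(rc[, 1]), , drop = FALSE]
}

#' Index a rail network against a landscape grid
#'
#' For every grid cell the network passes through, records each crossing edge
#' together with the arc-length position on that edge nearest the cell centre
#' and its distance. The index backs [entry_point()] and the per-cell
#' "has rail" flag used for route choice.
#'
#' @param network an `slf_network`.
#' @param landscape an `slf_landscape`.
#' @return a list with `index` (data frame: row, col, edge, arc_pos, dist) and
#'   `has_rail` (logical matrix).
#' @export
index_network <- function(network, landscape) {
  out <- list()
  for (ei in seq_along(network$edges)) {
    e <- network$edges[[ei]]
    cells <- NULL
    for (i in seq_len(nrow(e$verts) - 1L)) {
      cells <- rbind(cells, segment_cells(e$verts[i, ], e$verts[i + 1L, ],
                                          landscape))
    }
    if (is.null(cells) || nrow(cells) == 0L) next
    cells <- unique(cells)
    ctr <- cell_center(cells[, 1], cells[, 2], landscape)
    near <- t(vapply(seq_len(nrow(cells)), function(k)
      nearest_on_edge(e, ctr[k, 1], ctr[k, 2]), c(pos = 0, dist = 0)))
    out[[length(out) + 1L]] <- data.frame(
      row = cells[, 1], col = cells[, 2], edge = ei,
      arc_pos = near[, 1], dist = near[, 2])
  }
  idx <- if (length(out)) do.call(rbind, out)
  else data.frame(row = integer(), col = integer(), edge = integer(),
                  arc_pos = numeric(), dist = numeric())
  has_rail <- matrix(FALSE, landscape$n_rows, landscape$n_cols)
  has_rail[cbind(idx$row, idx$col)] <- TRUE
  list(index = idx, has_rail = has_rail)
}

# Nearest point on an edge polyline to (px, py): arc position and distance.
nearest_on_edge <- function(e, px, py) {
  px <- unname(px); py <- unname(py)
  best <- c(pos = 0, dist = Inf)
  for (i in seq_len(nrow(e$verts) - 1L)) {
    a <- e$verts[i, ]; b <- e$verts[i + 1L, ]
    ab <- b - a; len2 <- sum(ab^2)
    t <- if (len2 > 0) min(max(((px - a[1]) * ab[1] + (py - a[2]) * ab[2]) / len2, 0), 1) else 0
    q <- a + t * ab
    d <- sqrt((q[1] - px)^2 + (q[2] - py)^2)
    if (d < best["dist"])
      best <- c(pos = e$cum[i] + t * sqrt(len2), dist = d)
  }
  best
}

#' Boarding point for network dispersal from a cell
#'
#' Restricted to edges that cross the cell, returns the (edge, arc-length)
#' position nearest the cell centre — the point where a group boards the rail.
#'
#' @param cell length-2 vector (row, col), 1-based.
#' @param net_index result of [index_network()].
#' @return list with `edge` (edge index) and `arc_pos` (metres along it).
#' @export
entry_point <- function(cell, net_index) {
  idx <- net_index$index
  hits <- idx[idx$row == cell[1] & idx$col == cell[2], , drop = FALSE]
  if (nrow(hits) == 0L)
    stop(sprintf("no rail in cell (%d, %d)", cell[1], cell[2]))
  best <- hits[which.min(hits$dist), ]
  list(edge = best$edge, arc_pos = best$arc_pos)
}
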