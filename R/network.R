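#' Road network for urban travel-time modeling
#'
#' An undirected planar graph: nodes with projected-meter coordinates and
#' edges with lengths. Edge lengths default to the Euclidean distance
#' between their end nodes; supplied lengths are checked against that
#' distance within `length_tol` (relative) unless `check_lengths = FALSE`
#' (e.g. for generalized network data whose polyline lengths exceed the
#' node-to-node chord).
#'
#' @param nodes data frame: `id` (unique character), `x`, `y` (meters).
#' @param edges data frame: `from`, `to` (node ids), optional `length_m`,
#'   optional `road_class`.
#' @param length_tol relative tolerance for the length consistency check.
#' @param check_lengths set FALSE to accept lengths longer than the chord.
#' @return object of class `road_network`.
#' @export
road_network <- function(nodes, edges, length_tol = 0.01,
                         check_lengths = TRUE) {
  nodes$id <- as.character(nodes$id)
  if (anyDuplicated(nodes$id)) {
    stop_ra("duplicate node ids", "ra_network_error")
  }
  edges$from <- as.character(edges$from)
  edges$to <- as.character(edges$to)
  bad <- setdiff(c(edges$from, edges$to), nodes$id)
  if (length(bad) > 0) {
    stop_ra(sprintf("edge endpoint(s) not in nodes: %s",
                    paste(unique(bad), collapse = ", ")), "ra_network_error")
  }
  chord <- sqrt((nodes$x[match(edges$from, nodes$id)] -
                   nodes$x[match(edges$to, nodes$id)])^2 +
                (nodes$y[match(edges$from, nodes$id)] -
                   nodes$y[match(edges$to, nodes$id)])^2)
  if (is.null(edges$length_m)) {
    edges$length_m <- chord
  } else if (check_lengths) {
    off <- abs(edges$length_m - chord) > length_tol * pmax(chord, 1)
    if (any(off)) {
      stop_ra(sprintf(
        "edge length inconsistent with node coordinates for %d edge(s)",
        sum(off)), "ra_network_error")
    }
  }
  if (any(edges$length_m <= 0)) {
    stop_ra("edge lengths must be > 0", "ra_network_error")
  }
  if (is.null(edges$road_class)) {
    edges$road_class <- rep("unclassified", nrow(edges))
  }
  structure(list(nodes = nodes, edges = edges), class = "road_network")
}

#' @export
print.road_network <- function(x, ...) {
  cat(sprintf("road_network: %d nodes, %d edges, total length %.1f km\n",
              nrow(x$nodes), nrow(x$edges), sum(x$edges$length_m) / 1000))
  invisible(x)
}

.net_igraph <- function(net) {
  igraph::graph_from_data_frame(
    net$edges[, c("from", "to", "length_m")],
    directed = FALSE,
    vertices = net$nodes[, c("id", "x", "y")])
}

#' Snap a point to the nearest network node
#'
#' Nearest node by Euclidean distance; exact ties break to the smallest
#' node id so that snapping is deterministic.
#'
#' @param p numeric length-2 vector (x, y) or data frame with `x`, `y`.
#' @param net a `road_network`.
#' @return node id (character vector when `p` has several rows).
#' @export
snap_to_network <- function(p, net) {
  if (nrow(net$nodes) == 0) stop_ra("empty network", "ra_network_error")
  if (is.numeric(p) && is.null(dim(p))) p <- data.frame(x = p[1], y = p[2])
  vapply(seq_len(nrow(p)), function(i) {
    d2 <- (net$nodes$x - p$x[i])^2 + (net$nodes$y - p$y[i])^2
    cand <- net$nodes$id[d2 <= min(d2) + 1e-9]
    sort(cand)[1]
  }, character(1))
}

#' Urban travel-model configuration
#'
#' The urban model assumes clients reach facilities by public transport:
#' one fixed wait time for pick-up plus network travel at one average
#' speed. Defaults: 50 min wait, 10 km/h.
#'
#' @param wait_time_min minutes waited for transport pick-up (>= 0).
#' @param speed_kph average public-transport speed (> 0).
#' @return list of class `urban_model_config`.
#' @export
urban_model_config <- function(wait_time_min = 50, speed_kph = 10) {
  if (wait_time_min < 0) stop_ra("wait_time_min must be >= 0", "ra_config_error")
  if (speed_kph <= 0) stop_ra("speed_kph must be > 0", "ra_config_error")
  structure(list(wait_time_min = wait_time_min, speed_kph = speed_kph),
            class = "urban_model_config")
}

#' Urban one-way travel time to the nearest facility
#'
#' For each origin point: snap origin and facilities to their nearest
#' network nodes, take the shortest network path to the nearest facility
#' node, and convert to minutes as
#' `wait_time_min + 60 * (path_km) / speed_kph`. Origins disconnected from
#' every facility get `NA` with a warning.
#'
#' @param origins data frame of points (`x`, `y`), e.g. neighborhood
#'   centers.
#' @param fac_points data frame of facility points (`x`, `y`).
#' @param net a `road_network`.
#' @param cfg an [urban_model_config()].
#' @return numeric vector of minutes, one per origin.
#' @export
urban_travel_time <- function(origins, fac_points, net,
                              cfg = urban_model_config()) {
  if (nrow(fac_points) == 0) stop_ra("no facilities", "ra_no_facility_error")
  g <- .net_igraph(net)
  o_nodes <- snap_to_network(origins, net)
  f_nodes <- unique(snap_to_network(fac_points, net))
  d <- igraph::distances(g, v = o_nodes, to = f_nodes,
                         weights = igraph::E(g)$length_m,
                         algorithm = "dijkstra")
  best_m <- apply(d, 1, min)
  if (any(!is.finite(best_m))) {
    warn_ra(sprintf("%d origin(s) unreachable from every facility",
                    sum(!is.finite(best_m))), "ra_unreachable_warning")
  }
  minutes <- cfg$wait_time_min + 60 * (best_m / 1000) / cfg$speed_kph
  minutes[!is.finite(best_m)] <- NA_real_
  unname(minutes)
}
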