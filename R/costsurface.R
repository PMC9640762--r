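#' Travel speed schedule
#'
#' Maps road classes to motorized travel speeds and off-road surface
#' classes to walking speeds. The model assumes women walk across surfaces
#' without roads and switch to motorized transport on reaching a roadway,
#' so road speeds override surface speeds wherever both are present.
#' Default road speeds span 10-60 km/h by road class; default walking
#' speeds span 1-2.5 km/h by surface type.
#'
#' @param road named numeric vector: road class -> speed (km/h).
#' @param walk named numeric vector: surface class -> walking speed (km/h).
#' @return list of class `speed_schedule`.
#' @export
speed_schedule <- function(road = c(primary = 60, secondary = 40,
                                    tertiary = 25, track = 10),
                           walk = c(grassland = 2.5, shrubland = 1.8,
                                    wetland = 1.0)) {
  if (any(road <= 0) || any(walk <= 0)) {
    stop_ra("all speeds must be > 0", "ra_schedule_error")
  }
  structure(list(road = road, walk = walk), class = "speed_schedule")
}

.class_names <- function(r) {
  # class rasters carry integer codes plus a levels map (name -> code)
  v <- r$values
  if (!is.null(r$levels)) {
    nm <- names(r$levels)[match(v, r$levels)]
    nm[is.na(v)] <- NA
    matrix(nm, nrow(v), ncol(v))
  } else {
    matrix(ifelse(is.na(v), NA, as.character(v)), nrow(v), ncol(v))
  }
}

#' Build a traversal cost surface
#'
#' Combines a surface-class raster and an optional road-class raster into a
#' per-cell speed raster (km/h): the road speed where a road is present
#' (road overrides surface), the walking speed for the surface class
#' elsewhere. No-data surface cells stay no-data (impassable).
#'
#' Class rasters are `grid_raster`s of integer codes with a `levels` field
#' (named vector, class name -> code); every class occurring in a raster
#' must have a schedule entry.
#'
#' @param surface surface-class `grid_raster`.
#' @param roads road-class `grid_raster` aligned with `surface`, or NULL.
#' @param sched a [speed_schedule()].
#' @return a `grid_raster` of speeds (km/h), class `cost_surface`.
#' @export
build_cost_surface <- function(surface, roads = NULL,
                               sched = speed_schedule()) {
  if (!is.null(roads) && !.same_grid(surface, roads)) {
    stop_ra("surface and road rasters are not on the same grid",
            "ra_alignment_error")
  }
  scl <- .class_names(surface)
  unknown <- setdiff(unique(scl[!is.na(scl)]), names(sched$walk))
  if (length(unknown) > 0) {
    stop_ra(sprintf("no walking speed for surface class(es): %s",
                    paste(unknown, collapse = ", ")), "ra_schedule_error")
  }
  speed <- matrix(sched$walk[scl], nrow(surface$values), ncol(surface$values))
  if (!is.null(roads)) {
    rcl <- .class_names(roads)
    unknown <- setdiff(unique(rcl[!is.na(rcl)]), names(sched$road))
    if (length(unknown) > 0) {
      stop_ra(sprintf("no road speed for road class(es): %s",
                      paste(unknown, collapse = ", ")), "ra_schedule_error")
    }
    has_road <- !is.na(rcl)
    speed[has_road] <- sched$road[rcl[has_road]]
  }
  out <- grid_raster(speed, surface$cell_size_m, surface$xmin, surface$ymin)
  class(out) <- c("cost_surface", class(out))
  out
}

# Snap source points to passable cells. Returns cell linear indices
# (column-major over the value matrix).
.snap_sources <- function(cs, sources, max_snap_cells = 5) {
  v <- cs$values
  nr <- nrow(v); nc <- ncol(v)
  rc <- cell_of(cs, sources$x, sources$y)
  if (anyNA(rc$row)) {
    stop_ra(sprintf("source(s) outside the raster extent: %s",
                    paste(which(is.na(rc$row)), collapse = ", ")),
            "ra_source_error")
  }
  idx <- integer(nrow(rc))
  for (k in seq_len(nrow(rc))) {
    r0 <- rc$row[k]; c0 <- rc$col[k]
    if (!is.na(v[r0, c0])) { idx[k] <- (c0 - 1) * nr + r0; next }
    best <- NA_integer_; best_d <- Inf
    for (dr in -max_snap_cells:max_snap_cells) {
      for (dc in -max_snap_cells:max_snap_cells) {
        r1 <- r0 + dr; c1 <- c0 + dc
        if (r1 < 1 || r1 > nr || c1 < 1 || c1 > nc) next
        if (is.na(v[r1, c1])) next
        d <- dr * dr + dc * dc
        if (d < best_d) { best_d <- d; best <- (c1 - 1) * nr + r1 }
      }
    }
    if (is.na(best)) {
      stop_ra(sprintf(
        "source %d has no passable cell within %d cells", k, max_snap_cells),
        "ra_source_error")
    }
    idx[k] <- best
  }
  idx
}

#' Accumulate travel time over a cost surface
#'
#' Multi-source least-cost accumulation over the 8-connected cell graph:
#' the cost of stepping between adjacent cells is
#' `d * (t_a + t_b) / 2`, where `d` is the center-to-center distance
#' (cell size, or cell size * sqrt(2) diagonally) and `t_c` is the cell's
#' traversal time in minutes per meter (`60 / (1000 * speed_kph)`). Each
#' cell receives the minutes to the nearest source; source cells are 0;
#' impassable or unreachable cells are no-data.
#'
#' Sources falling on an impassable cell snap to the nearest passable cell
#' within `max_snap_cells` (error beyond that); sources outside the raster
#' are an error.
#'
#' @param cs a `cost_surface` (speeds in km/h).
#' @param sources data frame of source points (`x`, `y`), e.g. ready
#'   facilities.
#' @param max_snap_cells snap radius in cells for off-surface sources.
#' @return a `grid_raster` of minutes, class `travel_time_raster`.
#' @export
accumulate_travel_time <- function(cs, sources, max_snap_cells = 5) {
  v <- cs$values
  nr <- nrow(v); nc <- ncol(v); cell <- cs$cell_size_m
  if (all(is.na(v))) stop_ra("cost surface is entirely impassable",
                             "ra_source_error")
  src <- unique(.snap_sources(cs, sources, max_snap_cells))

  tpm <- 60 / (1000 * v)          # minutes per meter per cell
  passable <- which(!is.na(v))    # linear (column-major) indices
  vid <- match(seq_len(nr * nc), passable)  # cell -> vertex id or NA

  rows <- ((passable - 1) %% nr) + 1
  cols <- ((passable - 1) %/% nr) + 1
  edge_list <- list(); w_list <- list(); k <- 0
  for (off in list(c(1L, 0L, 1), c(0L, 1L, 1), c(1L, 1L, sqrt(2)),
                   c(-1L, 1L, sqrt(2)))) {
    r2 <- rows + off[1]; c2 <- cols + off[2]
    ok <- r2 >= 1 & r2 <= nr & c2 >= 1 & c2 <= nc
    tgt <- (c2[ok] - 1) * nr + r2[ok]
    src_cells <- passable[ok]
    keep <- !is.na(vid[tgt])
    a <- src_cells[keep]; b <- tgt[keep]
    if (length(a) == 0) next
    k <- k + 1
    edge_list[[k]] <- rbind(vid[a], vid[b])
    w_list[[k]] <- cell * off[3] * (tpm[a] + tpm[b]) / 2
  }
  minutes <- matrix(NA_real_, nr, nc)
  if (k > 0) {
    g <- igraph::make_graph(edges = as.vector(do.call(cbind, edge_list)),
                            n = length(passable), directed = FALSE)
    d <- igraph::distances(g, v = vid[src],
                           weights = unlist(w_list),
                           algorithm = "dijkstra")
    dm <- apply(d, 2, min)
    dm[!is.finite(dm)] <- NA_real_
    minutes[passable] <- dm
  } else {
    minutes[src] <- 0
  }
  out <- grid_raster(minutes, cell, cs$xmin, cs$ymin)
  class(out) <- c("travel_time_raster", class(out))
  out
}
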