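#' Generate synthetic facility survey records
#'
#' Draws each readiness component independently per facility at the given
#' pass rates, then fills the item-level checklist consistently with the
#' drawn component status (a failing component has at least one randomly
#' chosen item knocked out; a passing component has every item present).
#' Under independent components, the expected fraction of facilities ready
#' for regular removals is `general * hr_regular * equip_regular`.
#'
#' @param n number of facilities.
#' @param rates named list of pass probabilities in `[0, 1]`:
#'   `general`, `hr_regular`, `hr_ultrasound`, `equip_regular`,
#'   `equip_difficult` (the extra difficult-equipment block). Defaults are
#'   the study-condition marginals.
#' @param seed integer random seed.
#' @return a `facility_survey` data frame of `n` assessed facilities.
#' @export
gen_facilities <- function(n,
                           rates = list(general = 0.92, hr_regular = 1,
                                        hr_ultrasound = 0.18,
                                        equip_regular = 0.79,
                                        equip_difficult = 0.08),
                           seed = 1) {
  if (any(unlist(rates) < 0 | unlist(rates) > 1)) {
    stop_ra("component pass rates must be in [0, 1]", "ra_rate_error")
  }
  set.seed(seed)
  ids <- sprintf("SYN-%05d", seq_len(n))
  district <- sample(.districts, n, replace = TRUE)
  ftype <- sample(c("HEALTH_POST", "HEALTH_CENTER_I"), n, replace = TRUE,
                  prob = c(0.85, 0.15))
  df <- data.frame(facility_id = ids, district = district,
                   facility_type = ftype,
                   x = runif(n, 0, 50000), y = runif(n, 0, 50000),
                   assessed = TRUE, refers_to = NA_character_,
                   stringsAsFactors = FALSE)
  for (cl in c(.general_cols[1:4], .equip_cols)) df[[cl]] <- TRUE
  df$removal_days_per_week <- 5L
  df$n_trained_removal <- 1L
  df$n_trained_ultrasound <- 0L
  df$autoclave <- as.logical(rbinom(n, 1, 0.64))

  pass <- function(p) runif(n) < p
  g_ok <- pass(rates$general)
  hr_ok <- pass(rates$hr_regular)
  us_ok <- pass(rates$hr_ultrasound)
  eq_ok <- pass(rates$equip_regular)
  ed_ok <- pass(rates$equip_difficult)

  gen_items <- c(.general_cols[1:4], "days")
  core <- c("syringes", "local_anesthetic", "sterile_band_aids",
            "scalpel_with_blade", "curved_forceps", "straight_forceps")
  extra <- c("vasectomy_forceps", "ultrasound_machine", "sterile_towels",
             "examination_table", "sterile_surgical_drape",
             "sterile_equipment_tray")
  for (i in which(!g_ok)) {
    it <- sample(gen_items, 1)
    if (it == "days") df$removal_days_per_week[i] <- sample(0:4, 1)
    else df[[it]][i] <- FALSE
  }
  df$n_trained_removal[!hr_ok] <- 0L
  df$n_trained_ultrasound[us_ok] <- 1L + rbinom(sum(us_ok), 1, 0.3)
  for (i in which(!eq_ok)) {
    for (it in sample(core, sample(1:2, 1))) df[[it]][i] <- FALSE
  }
  for (i in which(!ed_ok)) {
    for (it in sample(extra, sample(1:2, 1))) df[[it]][i] <- FALSE
  }
  facility_survey(df)
}

#' Synthetic geography specification
#'
#' Parameters for the rural and urban scenario generators, with defaults
#' sized like a small two-district study area.
#'
#' @param n_rows,n_cols raster grid size (rural).
#' @param cell_size_m raster cell size in meters.
#' @param surface_mix named numeric vector of surface-class mixture weights
#'   (classes must have entries in the walking schedule).
#' @param smoothing number of smoothing passes for spatial clustering of
#'   surface classes (0 = independent cells).
#' @param road_spacing road grid spacing in cells (rural) — roads are
#'   burned along every `road_spacing`-th row and column.
#' @param road_classes character vector of road classes cycled across the
#'   burned grid lines.
#' @param population_total total population (women of reproductive age).
#' @param population_pattern "uniform" or "clustered".
#' @param n_facilities number of facilities to place.
#' @param n_neighborhoods number of neighborhood center points (urban).
#' @param grid_nx,grid_ny,grid_spacing_m urban road-grid dimensions.
#' @param seed integer random seed.
#' @return list of class `synthetic_geo_spec`.
#' @export
synthetic_geo_spec <- function(n_rows = 60, n_cols = 60, cell_size_m = 500,
                               surface_mix = c(grassland = 0.6,
                                               shrubland = 0.3,
                                               wetland = 0.1),
                               smoothing = 2,
                               road_spacing = 15,
                               road_classes = c("primary", "secondary",
                                                "tertiary", "track"),
                               population_total = 150000,
                               population_pattern = "clustered",
                               n_facilities = 8,
                               n_neighborhoods = 425,
                               grid_nx = 12, grid_ny = 12,
                               grid_spacing_m = 400,
                               seed = 1) {
  structure(as.list(environment()), class = "synthetic_geo_spec")
}

# von Neumann neighborhood mean, `passes` times; edges use the available
# neighbors only. Gives the surface-class field spatial autocorrelation.
.smooth_field <- function(m, passes) {
  nr <- nrow(m); nc <- ncol(m)
  for (p in seq_len(passes)) {
    s <- m
    cnt <- matrix(1, nr, nc)
    for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
      val <- matrix(0, nr, nc)
      one <- matrix(0, nr, nc)
      rs <- max(1, 1 + d[1]):min(nr, nr + d[1])
      cs <- max(1, 1 + d[2]):min(nc, nc + d[2])
      val[rs, cs] <- m[rs - d[1], cs - d[2]]
      one[rs, cs] <- 1
      s <- s + val
      cnt <- cnt + one
    }
    m <- s / cnt
  }
  m
}

#' Generate a synthetic rural geography
#'
#' Builds aligned class rasters for a rural cost-surface model: a spatially
#' clustered surface-class raster, a road raster burned along grid lines
#' (classes cycling through `spec$road_classes`), a population raster whose
#' cells sum exactly to `spec$population_total`, and facility points placed
#' on road cells. Runs are reproducible for a given `spec$seed`.
#'
#' @param spec a [synthetic_geo_spec()].
#' @return list: `surface`, `roads`, `population` (aligned `grid_raster`s),
#'   `facilities` (data frame `facility_id`, `x`, `y`), `spec`.
#' @export
gen_rural_scenario <- function(spec = synthetic_geo_spec()) {
  set.seed(spec$seed)
  nr <- spec$n_rows; nc <- spec$n_cols; cs <- spec$cell_size_m

  field <- .smooth_field(matrix(runif(nr * nc), nr, nc), spec$smoothing)
  br <- stats::quantile(field, cumsum(spec$surface_mix / sum(spec$surface_mix)))
  codes <- findInterval(field, c(-Inf, br[-length(br)]), rightmost.closed = FALSE)
  levels <- setNames(seq_along(spec$surface_mix), names(spec$surface_mix))
  surface <- grid_raster(matrix(as.numeric(codes), nr, nc), cs,
                         levels = levels)

  road_m <- matrix(NA_real_, nr, nc)
  rl <- setNames(seq_along(spec$road_classes), spec$road_classes)
  lines_r <- seq(ceiling(spec$road_spacing / 2), nr, by = spec$road_spacing)
  lines_c <- seq(ceiling(spec$road_spacing / 2), nc, by = spec$road_spacing)
  k <- 0
  for (r in lines_r) { k <- k + 1; road_m[r, ] <- rl[[1 + (k - 1) %% length(rl)]] }
  for (cc in lines_c) { k <- k + 1; road_m[, cc] <- rl[[1 + (k - 1) %% length(rl)]] }
  roads <- grid_raster(road_m, cs, levels = rl)

  w <- runif(nr * nc)
  if (spec$population_pattern == "clustered") {
    centers <- cbind(runif(4, 1, nr), runif(4, 1, nc))
    rows <- matrix(seq_len(nr), nr, nc)
    cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
    dens <- Reduce(`+`, lapply(seq_len(nrow(centers)), function(i) {
      exp(-((rows - centers[i, 1])^2 + (cols - centers[i, 2])^2) /
            (2 * (nr / 6)^2))
    }))
    w <- w * as.vector(dens)
  }
  pop_counts <- stats::rmultinom(1, spec$population_total, w)[, 1]
  population <- grid_raster(matrix(as.numeric(pop_counts), nr, nc), cs)

  road_cells <- which(!is.na(road_m))
  if (length(road_cells) == 0) {
    stop_ra("no passable road cell to place facilities on", "ra_gen_error")
  }
  fc <- sample(road_cells, min(spec$n_facilities, length(road_cells)))
  frow <- ((fc - 1) %% nr) + 1
  fcol <- ((fc - 1) %/% nr) + 1
  facilities <- data.frame(
    facility_id = sprintf("RUR-%02d", seq_along(fc)),
    x = (fcol - 0.5) * cs, y = (nr - frow + 0.5) * cs,
    stringsAsFactors = FALSE)

  list(surface = surface, roads = roads, population = population,
       facilities = facilities, spec = spec)
}

#' Generate a synthetic urban geography
#'
#' Builds a planar grid road network (`grid_nx` by `grid_ny` nodes at
#' `grid_spacing_m`), a rectangular boundary, `n_neighborhoods` neighborhood
#' center points uniform inside the boundary with populations summing to
#' `population_total`, and facility points at randomly chosen network
#' nodes. Runs are reproducible for a given `spec$seed`.
#'
#' @param spec a [synthetic_geo_spec()].
#' @return list: `network` (a `road_network`), `neighborhoods` (data frame
#'   `x`, `y`, `population`), `boundary` (ring matrix), `facilities`
#'   (data frame `facility_id`, `x`, `y`), `spec`.
#' @export
gen_urban_scenario <- function(spec = synthetic_geo_spec()) {
  if (spec$n_neighborhoods < 1) {
    stop_ra("at least one neighborhood required", "ra_gen_error")
  }
  set.seed(spec$seed)
  nx <- spec$grid_nx; ny <- spec$grid_ny; s <- spec$grid_spacing_m
  nodes <- expand.grid(ix = seq_len(nx) - 1, iy = seq_len(ny) - 1)
  nodes <- data.frame(id = sprintf("n%03d_%03d", nodes$ix, nodes$iy),
                      x = nodes$ix * s, y = nodes$iy * s,
                      stringsAsFactors = FALSE)
  edges <- list()
  for (ix in seq_len(nx) - 1) for (iy in seq_len(ny) - 1) {
    if (ix < nx - 1) {
      edges[[length(edges) + 1]] <- c(sprintf("n%03d_%03d", ix, iy),
                                      sprintf("n%03d_%03d", ix + 1, iy))
    }
    if (iy < ny - 1) {
      edges[[length(edges) + 1]] <- c(sprintf("n%03d_%03d", ix, iy),
                                      sprintf("n%03d_%03d", ix, iy + 1))
    }
  }
  em <- do.call(rbind, edges)
  net <- road_network(nodes, data.frame(from = em[, 1], to = em[, 2],
                                        road_class = "urban",
                                        stringsAsFactors = FALSE))
  xmax <- (nx - 1) * s; ymax <- (ny - 1) * s
  boundary <- cbind(x = c(0, xmax, xmax, 0), y = c(0, 0, ymax, ymax))

  nb <- data.frame(x = runif(spec$n_neighborhoods, 0, xmax),
                   y = runif(spec$n_neighborhoods, 0, ymax))
  w <- rlnorm(spec$n_neighborhoods, meanlog = 0, sdlog = 0.8)
  nb$population <- as.numeric(
    stats::rmultinom(1, spec$population_total, w)[, 1])

  fi <- sample(nrow(nodes), min(spec$n_facilities, nrow(nodes)))
  facilities <- data.frame(facility_id = sprintf("URB-%02d", seq_along(fi)),
                           x = nodes$x[fi], y = nodes$y[fi],
                           stringsAsFactors = FALSE)
  list(network = net, neighborhoods = nb, boundary = boundary,
       facilities = facilities, spec = spec)
}
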