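#' Planar grid raster
#'
#' Minimal regular-grid raster used for class, cost, population and travel
#' time surfaces: a numeric matrix (row 1 = northernmost row) with a square
#' cell size and the coordinates of the lower-left corner in projected
#' meters. `NA` is the no-data value.
#'
#' @param values numeric matrix.
#' @param cell_size_m cell edge length in meters (> 0).
#' @param xmin,ymin coordinates of the lower-left corner of the grid.
#' @param levels optional named integer vector (class name -> code) for
#'   class-coded rasters such as land-surface or road-class grids.
#' @return object of class `grid_raster`.
#' @export
grid_raster <- function(values, cell_size_m, xmin = 0, ymin = 0,
                        levels = NULL) {
  if (!is.matrix(values)) values <- as.matrix(values)
  if (!is.numeric(cell_size_m) || cell_size_m <= 0) {
    stop_ra("cell_size_m must be > 0", "ra_raster_error")
  }
  structure(list(values = values, cell_size_m = cell_size_m,
                 xmin = xmin, ymin = ymin, levels = levels),
            class = "grid_raster")
}

#' @export
dim.grid_raster <- function(x) dim(x$values)

#' @export
print.grid_raster <- function(x, ...) {
  v <- x$values[is.finite(x$values)]
  cat(sprintf("grid_raster: %d x %d cells of %g m, origin (%g, %g)\n",
              nrow(x$values), ncol(x$values), x$cell_size_m, x$xmin, x$ymin))
  if (length(v)) {
    cat(sprintf("  values: [%g, %g], %d no-data cell(s)\n", min(v), max(v),
                sum(is.na(x$values))))
  }
  invisible(x)
}

#' Cell-center coordinates of a grid raster
#' @param r a `grid_raster`.
#' @return list with matrices/vectors `x` (per column) and `y` (per row).
#' @export
cell_centers <- function(r) {
  n_r <- nrow(r$values); n_c <- ncol(r$values); cs <- r$cell_size_m
  list(x = r$xmin + (seq_len(n_c) - 0.5) * cs,
       y = r$ymin + (n_r - seq_len(n_r) + 0.5) * cs)
}

#' Locate points on a raster grid
#'
#' @param r a `grid_raster`.
#' @param x,y point coordinates (meters).
#' @return data frame `row`, `col` (NA when outside the grid extent).
#' @export
cell_of <- function(r, x, y) {
  cs <- r$cell_size_m
  col <- floor((x - r$xmin) / cs) + 1
  row <- nrow(r$values) - floor((y - r$ymin) / cs)
  outside <- col < 1 | col > ncol(r$values) | row < 1 | row > nrow(r$values)
  col[outside] <- NA_integer_
  row[outside] <- NA_integer_
  data.frame(row = as.integer(row), col = as.integer(col))
}

.same_grid <- function(a, b) {
  identical(dim(a$values), dim(b$values)) &&
    isTRUE(all.equal(a$cell_size_m, b$cell_size_m)) &&
    isTRUE(all.equal(c(a$xmin, a$ymin), c(b$xmin, b$ymin)))
}

#' Read / write Esri ASCII grid rasters
#'
#' Plain-text raster interchange: a six-line header (`ncols`, `nrows`,
#' `xllcorner`, `yllcorner`, `cellsize`, `NODATA_value`) followed by rows
#' of cell values, northernmost row first.
#'
#' @param path file path (.asc).
#' @return for `read_ascii_grid`, a `grid_raster`.
#' @export
read_ascii_grid <- function(path) {
  if (!file.exists(path)) stop_ra(paste("file not found:", path), "ra_io_error")
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1
  }
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA
  grid_raster(m, hdr$cellsize, xmin = hdr$xllcorner, ymin = hdr$yllcorner)
}

#' @rdname read_ascii_grid
#' @param r a `grid_raster` to write.
#' @param nodata numeric value written for `NA` cells.
#' @export
write_ascii_grid <- function(r, path, nodata = -9999) {
  m <- r$values
  m[is.na(m)] <- nodata
  hdr <- c(sprintf("ncols %d", ncol(m)), sprintf("nrows %d", nrow(m)),
           sprintf("xllcorner %.10g", r$xmin), sprintf("yllcorner %.10g", r$ymin),
           sprintf("cellsize %.10g", r$cell_size_m),
           sprintf("NODATA_value %g", nodata))
  body <- apply(m, 1, function(row) paste(format(row, trim = TRUE,
                                                 scientific = FALSE),
                                          collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read / write GeoJSON point layers
#'
#' Points are exchanged as a GeoJSON FeatureCollection of Point features in
#' a projected (meter) coordinate system; feature properties become data
#' frame columns.
#'
#' @param path file path (.geojson).
#' @return for `read_geojson_points`, a data frame with `x`, `y` and one
#'   column per property.
#' @export
read_geojson_points <- function(path) {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  feats <- gj$features
  coords <- t(vapply(feats, function(f) unlist(f$geometry$coordinates),
                     numeric(2)))
  df <- data.frame(x = coords[, 1], y = coords[, 2])
  props <- unique(unlist(lapply(feats, function(f) names(f$properties))))
  for (p in props) {
    df[[p]] <- unlist(lapply(feats, function(f) f$properties[[p]] %||% NA))
  }
  df
}

#' @rdname read_geojson_points
#' @param df data frame with columns `x`, `y` plus properties.
#' @export
write_geojson_points <- function(df, path) {
  feats <- lapply(seq_len(nrow(df)), function(i) {
    props <- as.list(df[i, setdiff(names(df), c("x", "y")), drop = FALSE])
    list(type = "Feature",
         geometry = list(type = "Point",
                         coordinates = c(df$x[i], df$y[i])),
         properties = props)
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a GeoJSON road network
#'
#' Reads a FeatureCollection of LineString features (projected meters) with
#' a `road_class` property and builds a [road_network()]: one node per
#' distinct vertex, one edge per consecutive vertex pair.
#'
#' @param path file path (.geojson).
#' @return a `road_network`.
#' @export
read_geojson_roads <- function(path) {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  verts <- list(); edges <- list()
  key <- function(x, y) sprintf("%.6f_%.6f", x, y)
  node_id <- new.env(parent = emptyenv())
  nxt <- 0L
  get_node <- function(x, y) {
    k <- key(x, y)
    if (is.null(node_id[[k]])) {
      nxt <<- nxt + 1L
      node_id[[k]] <- nxt
      verts[[nxt]] <<- c(x, y)
    }
    node_id[[k]]
  }
  for (f in gj$features) {
    cls <- f$properties$road_class %||% "unclassified"
    cc <- f$geometry$coordinates
    for (i in seq_len(length(cc) - 1)) {
      a <- get_node(cc[[i]][[1]], cc[[i]][[2]])
      b <- get_node(cc[[i + 1]][[1]], cc[[i + 1]][[2]])
      edges[[length(edges) + 1]] <- list(from = a, to = b, road_class = cls)
    }
  }
  vm <- do.call(rbind, verts)
  nodes <- data.frame(id = as.character(seq_len(nrow(vm))),
                      x = vm[, 1], y = vm[, 2], stringsAsFactors = FALSE)
  ed <- data.frame(from = as.character(vapply(edges, `[[`, 1, "from")),
                   to = as.character(vapply(edges, `[[`, 1, "to")),
                   road_class = vapply(edges, `[[`, "", "road_class"),
                   stringsAsFactors = FALSE)
  road_network(nodes, ed)
}
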