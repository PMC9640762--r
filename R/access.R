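.band_label <- function(k, band_width_min, max_bands) {
  h <- band_width_min / 60
  ifelse(is.na(k), "unreachable",
         ifelse(k >= max_bands, paste0(max_bands * h, "+"),
                paste0(k * h, "-", (k + 1) * h)))
}

#' Band travel minutes into hourly segments
#'
#' Assigns travel times to half-open bands `[60k, 60(k+1))` minutes; bands
#' at or beyond `max_bands` hours collapse into a single open-ended band
#' ("3+" by default). No-data (NA) maps to "unreachable".
#'
#' @param minutes numeric vector or a `travel_time_raster`.
#' @param band_width_min band width in minutes (default 60 = hourly).
#' @param max_bands number of closed bands before the open-ended band.
#' @return for numeric input, a character vector of band labels; for a
#'   raster, a `grid_raster` of band indices with a `levels` map
#'   (label -> index).
#' @export
band_minutes <- function(minutes, band_width_min = 60, max_bands = 3) {
  if (inherits(minutes, "grid_raster")) {
    m <- minutes$values
    if (any(m < 0, na.rm = TRUE)) {
      stop_ra("negative travel minutes", "ra_band_error")
    }
    k <- pmin(floor(m / band_width_min), max_bands)
    lv <- setNames(0:max_bands,
                   .band_label(0:max_bands, band_width_min, max_bands))
    return(grid_raster(k, minutes$cell_size_m, minutes$xmin, minutes$ymin,
                       levels = lv))
  }
  if (any(minutes < 0, na.rm = TRUE)) {
    stop_ra("negative travel minutes", "ra_band_error")
  }
  k <- pmin(floor(minutes / band_width_min), max_bands)
  .band_label(k, band_width_min, max_bands)
}

#' Band labels in order
#' @param band_width_min band width in minutes.
#' @param max_bands number of closed bands.
#' @return character vector of the closed-band labels plus the open band.
#' @export
band_labels <- function(band_width_min = 60, max_bands = 3) {
  .band_label(0:max_bands, band_width_min, max_bands)
}

#' Access table: population by travel-time band
#'
#' @param counts named numeric vector: population per band label.
#' @param unreachable population in unreachable locations (kept out of the
#'   band rows but in the proportion denominator).
#' @return data frame of class `access_table` with columns `band`,
#'   `population`, `percent` (one decimal; denominator is the total
#'   population including unreachable). Percentages are apportioned by
#'   largest remainder so the rows always total exactly 100.0.
#' @export
access_table <- function(counts, unreachable = 0) {
  total <- sum(counts) + unreachable
  if (total <= 0) stop_ra("zero total population", "ra_population_error")
  pop <- c(as.numeric(counts), if (unreachable > 0) unreachable)
  raw <- 1000 * pop / total               # tenths of a percent
  fl <- floor(raw + 1e-9)
  short <- round(1000 - sum(fl))
  ord <- order(-(raw - fl), seq_along(raw))
  if (short > 0) fl[ord[seq_len(short)]] <- fl[ord[seq_len(short)]] + 1
  out <- data.frame(band = c(names(counts),
                             if (unreachable > 0) "unreachable"),
                    population = pop,
                    percent = fl / 10,
                    stringsAsFactors = FALSE)
  attr(out, "total") <- total
  class(out) <- c("access_table", "data.frame")
  out
}

#' @export
print.access_table <- function(x, ...) {
  cat("One-way travel time bands (hours) vs population\n")
  print.data.frame(x, row.names = FALSE)
  cat(sprintf("Total %g (100.0)\n", attr(x, "total")))
  invisible(x)
}

#' Overlay population on travel-time bands
#'
#' Raster mode: `bands` is a band raster from [band_minutes()] aligned with
#' the population raster; each cell's population counts toward its band.
#' Vector mode: `bands` is a character vector of band labels (one per
#' spatial unit, e.g. neighborhood) and `pop` a numeric vector of the
#' units' populations — the unit's whole population takes the unit's band,
#' the convention used when travel time is computed at a neighborhood
#' center and applied to its entire Thiessen polygon.
#'
#' @param bands band raster or character vector of band labels.
#' @param pop population raster aligned with `bands`, or numeric vector.
#' @param band_width_min,max_bands banding parameters (for row ordering).
#' @return an [access_table()].
#' @export
population_by_band <- function(bands, pop, band_width_min = 60,
                               max_bands = 3) {
  labels <- band_labels(band_width_min, max_bands)
  if (inherits(bands, "grid_raster")) {
    if (!inherits(pop, "grid_raster") || !.same_grid(bands, pop)) {
      stop_ra("population raster not aligned with band raster",
              "ra_alignment_error")
    }
    k <- bands$values
    p <- pop$values
    p[is.na(p)] <- 0
    counts <- vapply(0:max_bands, function(b) sum(p[!is.na(k) & k == b]),
                     numeric(1))
    unreach <- sum(p[is.na(k)])
  } else {
    counts <- vapply(labels, function(lb) sum(pop[bands == lb]), numeric(1))
    unreach <- sum(pop[bands == "unreachable"])
  }
  access_table(setNames(counts, labels), unreachable = unreach)
}

#' Run the access model end to end
#'
#' Filters facilities to those ready at the requested level, then models
#' one-way travel time to the nearest ready facility with the sub-model
#' matching the geography, and overlays population into hourly bands.
#'
#' Readiness comes from [classify_readiness()] on the assessed facilities;
#' facilities that were never assessed take part only if
#' `assumed_levels` assigns them a level (e.g. a referral hospital known to
#' operate but not surveyed).
#'
#' @param facilities a `facility_survey` data frame (provides locations).
#' @param geography a list describing the study geography. Urban:
#'   `list(type = "urban", network = road_network, neighborhoods =
#'   data.frame(x, y, population), boundary = ring)`. Rural: `list(type =
#'   "rural", surface = grid_raster, roads = grid_raster or NULL,
#'   population = grid_raster)`.
#' @param level removal level facilities must be ready for: "REGULAR"
#'   (includes DIFFICULT-ready facilities) or "DIFFICULT".
#' @param readiness optional precomputed `readiness_result`; default
#'   classifies the assessed facilities.
#' @param criteria readiness criteria for the default classification.
#' @param urban_config an [urban_model_config()].
#' @param schedule a [speed_schedule()] for the rural cost surface.
#' @param assumed_levels named character vector facility_id -> level for
#'   unassessed facilities (default: excluded).
#' @param district restrict candidate facilities to one district (the
#'   urban and rural models are run per district); default uses all.
#' @param round_trip if TRUE, double the one-way minutes before banding
#'   (reporting option; off by default).
#' @return list of class `access_result`: `table` (an [access_table()]),
#'   `minutes` (per neighborhood, urban) or `travel_time` (raster, rural),
#'   `ready_ids`, `model`, `level`.
#' @export
run_access_model <- function(facilities, geography,
                             level = c("REGULAR", "DIFFICULT"),
                             readiness = NULL,
                             criteria = readiness_criteria(),
                             urban_config = urban_model_config(),
                             schedule = speed_schedule(),
                             assumed_levels = NULL,
                             district = NULL,
                             round_trip = FALSE) {
  level <- match.arg(level)
  if (!is.null(district)) {
    facilities <- facilities[facilities$district %in% district, ,
                             drop = FALSE]
  }
  assessed <- facilities[facilities$assessed, , drop = FALSE]
  if (is.null(readiness)) readiness <- classify_readiness(assessed, criteria)
  lev <- setNames(readiness$level, readiness$facility_id)
  if (!is.null(assumed_levels)) {
    lev[names(assumed_levels)] <- assumed_levels
  }
  lev <- lev[names(lev) %in% facilities$facility_id]
  ready_ids <- names(lev)[ready_at(lev, level)]
  if (length(ready_ids) == 0) {
    stop_ra(sprintf("no facility ready for %s removals", level),
            "ra_no_facility_error")
  }
  fac_pts <- facilities[match(ready_ids, facilities$facility_id),
                        c("x", "y")]

  mult <- if (round_trip) 2 else 1
  if (geography$type == "urban") {
    minutes <- mult * urban_travel_time(geography$neighborhoods, fac_pts,
                                        geography$network, urban_config)
    bands <- band_minutes(ifelse(is.na(minutes), NA, minutes))
    tab <- population_by_band(bands, geography$neighborhoods$population)
    res <- list(table = tab, minutes = minutes, ready_ids = ready_ids,
                model = "urban", level = level)
  } else if (geography$type == "rural") {
    cs <- build_cost_surface(geography$surface, geography$roads, schedule)
    tt <- accumulate_travel_time(cs, fac_pts)
    if (round_trip) tt$values <- tt$values * 2
    bands <- band_minutes(tt)
    tab <- population_by_band(bands, geography$population)
    res <- list(table = tab, travel_time = tt, bands = bands,
                ready_ids = ready_ids, model = "rural", level = level)
  } else {
    stop_ra(sprintf("unknown geography type '%s'", geography$type),
            "ra_config_error")
  }
  class(res) <- "access_result"
  res
}

#' @export
print.access_result <- function(x, ...) {
  cat(sprintf("Access model (%s, level %s): %d ready facility(ies)\n",
              x$model, x$level, length(x$ready_ids)))
  print(x$table)
  invisible(x)
}
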