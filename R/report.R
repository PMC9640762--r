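#' Write the readiness report
#'
#' Runs the readiness classification on a facility file or table and writes
#' two CSVs: the by-component district summary (whole percentages) and the
#' per-facility component booleans and level.
#'
#' @param facilities path to a facility CSV/JSON file, or a
#'   `facility_survey` data frame.
#' @param out_dir output directory (created if absent).
#' @param criteria a `readiness_criteria` list or a path to a criteria
#'   JSON file.
#' @return named character vector of the files written, invisibly.
#' @export
run_readiness_report <- function(facilities, out_dir = ".",
                                 criteria = readiness_criteria()) {
  if (is.character(facilities)) facilities <- read_facilities(facilities)
  if (is.character(criteria)) criteria <- read_criteria(criteria)
  if (nrow(facilities) == 0 || !any(facilities$assessed)) {
    stop_ra("no assessed facilities in input", "ra_empty_input_error")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  s <- summarize_readiness(facilities, criteria)
  r <- classify_readiness(facilities[facilities$assessed, ], criteria)
  paths <- c(summary = file.path(out_dir, "readiness_summary.csv"),
             facility = file.path(out_dir, "readiness_by_facility.csv"))
  write.csv(as.data.frame(s), paths[["summary"]], row.names = FALSE)
  write.csv(as.data.frame(r), paths[["facility"]], row.names = FALSE)
  message(sprintf("readiness: %d facilities assessed; regular %d%%, difficult %d%%",
                  sum(facilities$assessed),
                  s$Total[s$row == "Regular removals"],
                  s$Total[s$row == "Difficult removals"]))
  invisible(paths)
}

#' Write the referral network report
#'
#' Builds referral networks and the rationality audit and writes two CSVs:
#' the network listing (receiving facility, size, member ids) and the
#' role/rationality summary.
#'
#' @inheritParams run_readiness_report
#' @return named character vector of the files written, invisibly.
#' @export
run_referral_report <- function(facilities, out_dir = ".",
                                criteria = readiness_criteria()) {
  if (is.character(facilities)) facilities <- read_facilities(facilities)
  if (is.character(criteria)) criteria <- read_criteria(criteria)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  nets <- build_networks(facilities)
  r <- classify_readiness(facilities[facilities$assessed, ], criteria)
  rat <- assess_rationality(nets, r, facilities)
  net_df <- data.frame(
    receiving_id = nets$networks$receiving_id,
    size = nets$networks$size,
    member_ids = vapply(nets$networks$member_ids, paste, "", collapse = ";"),
    stringsAsFactors = FALSE)
  rc <- rat$role_counts
  e <- rat$endpoints
  summary_df <- data.frame(
    statistic = c("n_referring", "n_receiving", "n_standalone",
                  "n_assessed_receiving_or_standalone",
                  "n_regular_ready_endpoints", "n_difficult_ready_endpoints"),
    value = c(rc[["REFERRING"]], rc[["RECEIVING"]], rc[["STANDALONE"]],
              e[["n_assessed"]], e[["regular_ready"]],
              e[["difficult_ready"]]))
  paths <- c(networks = file.path(out_dir, "referral_networks.csv"),
             summary = file.path(out_dir, "referral_summary.csv"),
             receiving = file.path(out_dir, "receiving_readiness.csv"))
  write.csv(net_df, paths[["networks"]], row.names = FALSE)
  write.csv(summary_df, paths[["summary"]], row.names = FALSE)
  write.csv(rat$receiving, paths[["receiving"]], row.names = FALSE)
  message(sprintf("referral: %d network(s), sizes %s",
                  nrow(net_df), paste(net_df$size, collapse = ", ")))
  invisible(paths)
}

#' Write the access-model report
#'
#' Runs [run_access_model()] and writes the banded access table as CSV
#' (four hourly band rows plus a Total row at 100.0), the travel-time
#' raster as an ASCII grid (rural model), and per-neighborhood minutes as
#' GeoJSON points (urban model).
#'
#' @inheritParams run_readiness_report
#' @param geography geography bundle (see [run_access_model()]).
#' @param level "REGULAR" or "DIFFICULT".
#' @param ... passed to [run_access_model()].
#' @return named character vector of the files written, invisibly.
#' @export
run_access_report <- function(facilities, geography, level = "REGULAR",
                              out_dir = ".", criteria = readiness_criteria(),
                              ...) {
  if (is.character(facilities)) facilities <- read_facilities(facilities)
  if (is.character(criteria)) criteria <- read_criteria(criteria)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- run_access_model(facilities, geography, level = level,
                          criteria = criteria, ...)
  tab <- as.data.frame(res$table)
  tab <- rbind(tab, data.frame(band = "Total",
                               population = attr(res$table, "total"),
                               percent = 100.0))
  paths <- c(table = file.path(out_dir,
                               sprintf("access_table_%s.csv", tolower(level))))
  write.csv(tab, paths[["table"]], row.names = FALSE)
  if (res$model == "rural") {
    paths[["travel_time"]] <- file.path(
      out_dir, sprintf("travel_time_%s.asc", tolower(level)))
    write_ascii_grid(res$travel_time, paths[["travel_time"]])
  } else {
    paths[["minutes"]] <- file.path(
      out_dir, sprintf("neighborhood_minutes_%s.geojson", tolower(level)))
    nb <- geography$neighborhoods
    nb$minutes <- res$minutes
    write_geojson_points(nb, paths[["minutes"]])
  }
  message(sprintf("access (%s, %s): %d ready facility(ies)",
                  res$model, level, length(res$ready_ids)))
  invisible(paths)
}
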