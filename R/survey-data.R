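#' @importFrom utils read.csv write.csv
#' @importFrom stats setNames runif rbinom rlnorm
NULL

# Column schema for a facility survey table. Identity columns are always
# required; checklist columns must exist but may be NA for facilities that
# were never assessed (known only as referral destinations).
.id_cols <- c("facility_id", "district", "facility_type", "x", "y",
              "assessed", "refers_to")
.general_cols <- c("running_water", "decontamination_buckets", "safety_boxes",
                   "soap", "removal_days_per_week")
.staff_cols <- c("n_trained_removal", "n_trained_ultrasound")
.equip_cols <- c("syringes", "local_anesthetic", "sterile_band_aids",
                 "scalpel_with_blade", "curved_forceps", "straight_forceps",
                 "antiseptic", "cotton_balls", "sterile_gauze",
                 "vasectomy_forceps", "ultrasound_machine", "sterile_towels",
                 "examination_table", "sterile_surgical_drape",
                 "sterile_equipment_tray")
.bool_cols <- c(.general_cols[1:4], .equip_cols, "autoclave")
.count_cols <- c("removal_days_per_week", .staff_cols)

.districts <- c("DAKAR_CENTRE", "KOLDA")
.facility_types <- c("HEALTH_POST", "HEALTH_CENTER_I", "HEALTH_CENTER_II",
                     "HOSPITAL")

#' Facility survey table columns
#'
#' Column names of the flat facility survey schema, in canonical order.
#' `autoclave` is an optional reporting-only column; all other checklist
#' columns are required (values may be `NA` when `assessed` is `FALSE`).
#'
#' @return character vector of column names.
#' @export
facility_columns <- function() {
  c(.id_cols, .general_cols, .staff_cols, .equip_cols, "autoclave")
}

#' Construct a validated facility survey table
#'
#' Wraps a data frame of one-row-per-facility survey records, checking the
#' structural contract: all required columns present, `facility_id` unique,
#' and every `refers_to` naming another facility in the same table.
#'
#' @param df data frame following the schema of [facility_columns()].
#' @return a `facility_survey` data frame (row order preserved).
#' @export
facility_survey <- function(df) {
  required <- setdiff(facility_columns(), "autoclave")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop_ra(sprintf("missing required column(s): %s",
                    paste(missing, collapse = ", ")),
            "ra_schema_error")
  }
  if (!"autoclave" %in% names(df)) df$autoclave <- NA
  df <- df[, facility_columns()]
  df$facility_id <- as.character(df$facility_id)
  df$district <- as.character(df$district)
  df$facility_type <- as.character(df$facility_type)
  df$refers_to <- as.character(df$refers_to)
  df$assessed <- as.logical(df$assessed)
  for (cl in .bool_cols) df[[cl]] <- as.logical(df[[cl]])
  for (cl in .count_cols) df[[cl]] <- as.integer(df[[cl]])

  dup <- unique(df$facility_id[duplicated(df$facility_id)])
  if (length(dup) > 0) {
    stop_ra(sprintf("duplicate facility_id: %s", paste(dup, collapse = ", ")),
            "ra_uniqueness_error")
  }
  ref <- df$refers_to[!is.na(df$refers_to)]
  bad <- setdiff(ref, df$facility_id)
  self <- df$facility_id[!is.na(df$refers_to) &
                           df$refers_to == df$facility_id]
  if (length(bad) > 0 || length(self) > 0) {
    stop_ra(sprintf(
      "invalid refers_to link(s): %s",
      paste(c(sprintf("unknown destination '%s'", bad),
              sprintf("'%s' refers to itself", self)), collapse = "; ")),
      "ra_referential_error")
  }
  class(df) <- c("facility_survey", "data.frame")
  df
}

#' Read facility survey records
#'
#' Reads a facility table from CSV (booleans coded 0/1) or JSON (array of
#' flat objects; absent fields read as `NA`) and validates it with
#' [facility_survey()]. File row/object order is preserved.
#'
#' @param path file path.
#' @param format "csv" or "json"; default guessed from the file extension.
#' @return a `facility_survey` data frame.
#' @export
read_facilities <- function(path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (!file.exists(path)) stop_ra(paste("file not found:", path), "ra_io_error")
  if (format == "csv") {
    df <- read.csv(path, stringsAsFactors = FALSE, na.strings = c("NA", ""))
  } else {
    df <- as.data.frame(jsonlite::fromJSON(path), stringsAsFactors = FALSE)
  }
  if ("refers_to" %in% names(df) && !is.character(df$refers_to)) {
    df$refers_to <- as.character(df$refers_to)
  }
  facility_survey(df)
}

#' Write facility survey records
#'
#' Inverse of [read_facilities()]: CSV with booleans as 0/1, or JSON as an
#' array of flat objects with `NA` written as `null`.
#'
#' @param facilities a `facility_survey` data frame.
#' @param path output file path.
#' @param format "csv" or "json"; default guessed from the extension.
#' @return `path`, invisibly.
#' @export
write_facilities <- function(facilities, path,
                             format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  df <- as.data.frame(facilities)
  if (format == "csv") {
    for (cl in .bool_cols) df[[cl]] <- as.integer(df[[cl]])
    write.csv(df, path, row.names = FALSE, na = "NA")
  } else {
    jsonlite::write_json(df, path, dataframe = "rows", na = "null",
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Validate facility records against the survey invariants
#'
#' Unlike the structural checks in [facility_survey()] (which throw), this
#' audits value-level invariants and returns every violation as report
#' content: out-of-range counts, non-enum districts or facility types,
#' missing checklist values on assessed facilities, and (warning severity)
#' referral links reported by facilities that were never assessed.
#'
#' @param facilities a `facility_survey` data frame.
#' @return data frame with columns `facility_id`, `field`, `severity`
#'   ("error" or "warning"), `message`; zero rows iff the dataset is valid.
#' @export
validate_facilities <- function(facilities) {
  rows <- list()
  add <- function(id, field, severity, message) {
    rows[[length(rows) + 1]] <<- data.frame(
      facility_id = id, field = field, severity = severity,
      message = message, stringsAsFactors = FALSE)
  }
  f <- facilities
  for (i in seq_len(nrow(f))) {
    id <- f$facility_id[i]
    if (!f$district[i] %in% .districts)
      add(id, "district", "error",
          sprintf("unknown district '%s'", f$district[i]))
    if (!f$facility_type[i] %in% .facility_types)
      add(id, "facility_type", "error",
          sprintf("unknown facility_type '%s'", f$facility_type[i]))
    if (!is.finite(f$x[i]) || !is.finite(f$y[i]))
      add(id, "location", "error", "non-finite coordinates")
    d <- f$removal_days_per_week[i]
    if (!is.na(d) && (d < 0 || d > 7))
      add(id, "removal_days_per_week", "error",
          sprintf("removal_days_per_week = %d outside [0, 7]", d))
    for (cl in .staff_cols) {
      v <- f[[cl]][i]
      if (!is.na(v) && v < 0)
        add(id, cl, "error", sprintf("%s = %d is negative", cl, v))
    }
    if (isTRUE(f$assessed[i])) {
      checklist <- c(.general_cols, .staff_cols, .equip_cols)
      miss <- checklist[vapply(checklist, function(cl) is.na(f[[cl]][i]),
                               logical(1))]
      if (length(miss) > 0)
        add(id, paste(miss, collapse = ","), "error",
            "assessed facility with missing checklist value(s)")
    } else if (!is.na(f$refers_to[i])) {
      add(id, "refers_to", "warning",
          "unassessed facility reports a referral destination")
    }
  }
  if (length(rows) == 0) {
    return(data.frame(facility_id = character(), field = character(),
                      severity = character(), message = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' @export
print.facility_survey <- function(x, ...) {
  cat(sprintf("Facility survey: %d facilities (%d assessed) in %d district(s)\n",
              nrow(x), sum(x$assessed), length(unique(x$district))))
  NextMethod()
}
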