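#' Default readiness criteria table
#'
#' The conjunctive SARA-style criteria for classifying a facility as ready
#' for regular or difficult implant removals, expressed as data so the
#' scheme can be adapted. Three components:
#'
#' \describe{
#'   \item{general}{infection-prevention items (running water,
#'     decontamination buckets, safety boxes, soap) all present, and
#'     removals offered at least `min_days_per_week` days per week.}
#'   \item{human resources}{at least one provider trained in implant
#'     removal; difficult removals additionally need at least one provider
#'     trained to use ultrasound.}
#'   \item{equipment}{all regular-removal instruments and consumables
#'     observed, with the sterile-dressing requirement satisfied by any one
#'     of the `equipment_any_of` alternative groups; difficult removals
#'     additionally need every item in `equipment_difficult_extra`.}
#' }
#'
#' The sterile-dressing rule has two published readings; `gauze_rule`
#' selects between them:
#' * `"gauze_or_antiseptic_cotton"` (default): sterile gauze, OR antiseptic
#'   AND cotton balls.
#' * `"antiseptic_and_cotton_or_gauze"`: antiseptic AND (cotton balls OR
#'   sterile gauze).
#'
#' @param gauze_rule which reading of the sterile-dressing requirement to
#'   encode in `equipment_any_of`.
#' @return a list of class `readiness_criteria`.
#' @export
readiness_criteria <- function(gauze_rule = c("gauze_or_antiseptic_cotton",
                                              "antiseptic_and_cotton_or_gauze")) {
  gauze_rule <- match.arg(gauze_rule)
  any_of <- switch(gauze_rule,
    gauze_or_antiseptic_cotton = list(
      "sterile_gauze", c("antiseptic", "cotton_balls")),
    antiseptic_and_cotton_or_gauze = list(
      c("antiseptic", "cotton_balls"), c("antiseptic", "sterile_gauze")))
  structure(list(
    general_items = c("running_water", "decontamination_buckets",
                      "safety_boxes", "soap"),
    min_days_per_week = 5,
    hr_regular_min_removal_trained = 1,
    hr_difficult_min_ultrasound_trained = 1,
    equipment_regular = c("syringes", "local_anesthetic", "sterile_band_aids",
                          "scalpel_with_blade", "curved_forceps",
                          "straight_forceps"),
    equipment_any_of = any_of,
    equipment_difficult_extra = c("vasectomy_forceps", "ultrasound_machine",
                                  "sterile_towels", "examination_table",
                                  "sterile_surgical_drape",
                                  "sterile_equipment_tray"),
    gauze_rule = gauze_rule
  ), class = "readiness_criteria")
}

#' Read a readiness criteria table from a JSON file
#'
#' @param path JSON file as written by [write_criteria()].
#' @return a `readiness_criteria` list.
#' @export
read_criteria <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  crit <- readiness_criteria()
  scalar <- c("min_days_per_week", "hr_regular_min_removal_trained",
              "hr_difficult_min_ultrasound_trained", "gauze_rule")
  vec <- c("general_items", "equipment_regular", "equipment_difficult_extra")
  for (nm in intersect(names(raw), scalar)) crit[[nm]] <- raw[[nm]]
  for (nm in intersect(names(raw), vec)) {
    crit[[nm]] <- as.character(unlist(raw[[nm]]))
  }
  if (!is.null(raw$equipment_any_of)) {
    crit$equipment_any_of <- lapply(raw$equipment_any_of,
                                    function(g) as.character(unlist(g)))
  }
  crit
}

#' Write a readiness criteria table to JSON
#' @param criteria a `readiness_criteria` list.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_criteria <- function(criteria, path) {
  jsonlite::write_json(unclass(criteria), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

.check_assessed <- function(facilities) {
  if (any(!facilities$assessed)) {
    stop_ra(sprintf(
      "readiness is not assessable for unassessed facility(ies): %s",
      paste(facilities$facility_id[!facilities$assessed], collapse = ", ")),
      "ra_not_assessable_error")
  }
}

.all_true <- function(facilities, cols) {
  if (length(cols) == 0) return(rep(TRUE, nrow(facilities)))
  Reduce(`&`, lapply(cols, function(cl) facilities[[cl]]))
}

#' General service readiness
#'
#' TRUE iff all infection-prevention items are present and implant removals
#' are offered at least the minimum number of days per week (default 5).
#' Vectorized over the rows of `facilities`.
#'
#' @param facilities a `facility_survey` data frame (all rows assessed).
#' @param criteria a `readiness_criteria` list.
#' @return logical vector, one element per facility.
#' @export
general_service_ready <- function(facilities, criteria = readiness_criteria()) {
  .check_assessed(facilities)
  .all_true(facilities, criteria$general_items) &
    facilities$removal_days_per_week >= criteria$min_days_per_week
}

#' Human resources readiness
#'
#' Regular removals require at least one provider trained in implant
#' removal; difficult removals additionally require at least one provider
#' trained in ultrasound use.
#'
#' @inheritParams general_service_ready
#' @param level "REGULAR" or "DIFFICULT".
#' @return logical vector, one element per facility.
#' @export
human_resources_ready <- function(facilities, level = c("REGULAR", "DIFFICULT"),
                                  criteria = readiness_criteria()) {
  level <- match.arg(level)
  .check_assessed(facilities)
  ok <- facilities$n_trained_removal >= criteria$hr_regular_min_removal_trained
  if (level == "DIFFICULT") {
    ok <- ok & facilities$n_trained_ultrasound >=
      criteria$hr_difficult_min_ultrasound_trained
  }
  ok
}

#' Minimum equipment readiness
#'
#' Regular removals require every instrument/consumable in the regular
#' list plus the sterile-dressing alternative rule; difficult removals
#' require the regular set plus every additional difficult-removal item
#' (modified vasectomy forceps, ultrasound machine, sterile towels,
#' examination table, sterile surgical drape, sterile equipment tray).
#'
#' @inheritParams human_resources_ready
#' @return logical vector, one element per facility.
#' @export
equipment_ready <- function(facilities, level = c("REGULAR", "DIFFICULT"),
                            criteria = readiness_criteria()) {
  level <- match.arg(level)
  .check_assessed(facilities)
  ok <- .all_true(facilities, criteria$equipment_regular)
  any_ok <- Reduce(`|`, lapply(criteria$equipment_any_of,
                               function(g) .all_true(facilities, g)))
  ok <- ok & any_ok
  if (level == "DIFFICULT") {
    ok <- ok & .all_true(facilities, criteria$equipment_difficult_extra)
  }
  ok
}

#' Classify facility readiness level
#'
#' Applies all three components and assigns each assessed facility a level:
#' `DIFFICULT` if every regular and difficult criterion holds, else
#' `REGULAR` if every regular criterion holds, else `NOT_READY`.
#'
#' @inheritParams general_service_ready
#' @return data frame of class `readiness_result` with one row per
#'   facility: the five component booleans and `level`.
#' @export
classify_readiness <- function(facilities, criteria = readiness_criteria()) {
  .check_assessed(facilities)
  res <- data.frame(
    facility_id = facilities$facility_id,
    general_ok = general_service_ready(facilities, criteria),
    hr_regular_ok = human_resources_ready(facilities, "REGULAR", criteria),
    hr_difficult_ok = human_resources_ready(facilities, "DIFFICULT", criteria),
    equip_regular_ok = equipment_ready(facilities, "REGULAR", criteria),
    equip_difficult_ok = equipment_ready(facilities, "DIFFICULT", criteria),
    stringsAsFactors = FALSE)
  regular <- res$general_ok & res$hr_regular_ok & res$equip_regular_ok
  difficult <- regular & res$hr_difficult_ok & res$equip_difficult_ok
  res$level <- ifelse(difficult, "DIFFICULT",
                      ifelse(regular, "REGULAR", "NOT_READY"))
  class(res) <- c("readiness_result", "data.frame")
  res
}

#' Is a facility ready at (at least) a given level?
#' @param level_vec character vector of levels from [classify_readiness()].
#' @param level required level, "REGULAR" or "DIFFICULT".
#' @return logical vector.
#' @export
ready_at <- function(level_vec, level = c("REGULAR", "DIFFICULT")) {
  level <- match.arg(level)
  if (level == "REGULAR") level_vec %in% c("REGULAR", "DIFFICULT")
  else level_vec == "DIFFICULT"
}

# Rows of the by-component summary table, in publication order. Each row is
# (label, section, statistic function over a facility_survey subset).
.summary_rows <- function(criteria) {
  item <- function(cl) function(f, r) mean(f[[cl]])
  list(
    list("Regular removals", "level",
         function(f, r) mean(ready_at(r$level, "REGULAR"))),
    list("General service readiness", "component",
         function(f, r) mean(r$general_ok)),
    list("Running water", "item", item("running_water")),
    list("Decontamination buckets", "item", item("decontamination_buckets")),
    list("Safety boxes", "item", item("safety_boxes")),
    list("Soap", "item", item("soap")),
    list("Facility offers implant removals 5+ days per week", "item",
         function(f, r) mean(f$removal_days_per_week >=
                               criteria$min_days_per_week)),
    list("Human resources: 1+ staff trained in implant removal", "component",
         function(f, r) mean(r$hr_regular_ok)),
    list("Minimum equipment (regular)", "component",
         function(f, r) mean(r$equip_regular_ok)),
    list("Syringes", "item", item("syringes")),
    list("Local anesthetic", "item", item("local_anesthetic")),
    list("Sterile band aids", "item", item("sterile_band_aids")),
    list("Scalpel with blade", "item", item("scalpel_with_blade")),
    list("Curved forceps", "item", item("curved_forceps")),
    list("Straight forceps", "item", item("straight_forceps")),
    list("Sterile gauze, or antiseptic and cotton balls", "item",
         function(f, r) {
       mean(Reduce(`|`, lapply(criteria$equipment_any_of,
                               function(g) .all_true(f, g))))
         }),
    list("Difficult removals", "level",
         function(f, r) mean(ready_at(r$level, "DIFFICULT"))),
    list("Human resources: 1+ staff trained to use ultrasound", "component",
         function(f, r) mean(r$hr_difficult_ok)),
    list("Minimum equipment (difficult)", "component",
         function(f, r) mean(r$equip_difficult_ok)),
    list("Modified vasectomy forceps", "item", item("vasectomy_forceps")),
    list("Ultrasound", "item", item("ultrasound_machine")),
    list("Sterile towels", "item", item("sterile_towels")),
    list("Examination table", "item", item("examination_table")),
    list("Sterile dry surgical drape", "item", item("sterile_surgical_drape")),
    list("Sterile equipment tray", "item", item("sterile_equipment_tray"))
  )
}

#' Summarize readiness by district
#'
#' Builds the by-component readiness summary: one row per checklist item,
#' component and level, one column of whole percentages per district plus a
#' Total column. Unassessed facilities are excluded from all denominators.
#' Percentages use half-away-from-zero rounding ([round_half_up()]).
#'
#' @inheritParams general_service_ready
#' @param facilities a `facility_survey` data frame; unassessed rows are
#'   dropped from the summary (at least one assessed row required).
#' @return data frame of class `readiness_summary`: `row`, `section`, one
#'   integer percent column per district, `Total`. Attribute `n` holds the
#'   per-district denominators.
#' @export
summarize_readiness <- function(facilities, criteria = readiness_criteria()) {
  f <- facilities[facilities$assessed, , drop = FALSE]
  if (nrow(f) == 0) {
    stop_ra("no assessed facilities to summarize", "ra_empty_input_error")
  }
  r <- classify_readiness(f, criteria)
  districts <- unique(f$district)
  rows <- .summary_rows(criteria)
  groups <- c(setNames(lapply(districts, function(d) f$district == d),
                       districts),
              list(Total = rep(TRUE, nrow(f))))
  out <- data.frame(row = vapply(rows, `[[`, "", 1),
                    section = vapply(rows, `[[`, "", 2),
                    stringsAsFactors = FALSE)
  for (g in names(groups)) {
    sel <- groups[[g]]
    fg <- f[sel, , drop = FALSE]
    rg <- r[sel, , drop = FALSE]
    out[[g]] <- vapply(rows, function(row) pct(row[[3]](fg, rg) * nrow(fg),
                                               nrow(fg)), numeric(1))
  }
  attr(out, "n") <- vapply(groups, sum, integer(1))
  class(out) <- c("readiness_summary", "data.frame")
  out
}

#' Additional service indicators (reported, never scored)
#'
#' Share of assessed facilities with a functioning autoclave and with at
#' least two providers trained in implant removal. These indicators are
#' reported alongside the readiness table but never enter the readiness
#' classification.
#'
#' @param facilities a `facility_survey` data frame.
#' @return named numeric vector of whole percentages.
#' @export
additional_indicators <- function(facilities) {
  f <- facilities[facilities$assessed, , drop = FALSE]
  n <- nrow(f)
  c(autoclave = pct(sum(f$autoclave, na.rm = TRUE), n),
    two_plus_removal_trained = pct(sum(f$n_trained_removal >= 2), n))
}

#' @export
print.readiness_summary <- function(x, ...) {
  n <- attr(x, "n")
  cat("Readiness by component (% of assessed facilities)\n")
  cat(paste(sprintf("%s (n = %d)", names(n), n), collapse = " | "), "\n")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}
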