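#' Deterministic two-district study fixture
#'
#' Builds a frozen 40-facility dataset: 13 assessed facilities in the urban
#' district (Dakar Centre), 26 in the rural district (Kolda), plus one
#' hospital known only as a referral destination (never assessed). The
#' item-level checklist values are one feasible joint assignment, derived
#' by constraint satisfaction, that reproduces every published per-district
#' component marginal under half-away-from-zero rounding, and the referral
#' links encode the published star topology: three networks of 20, 7 and 4
#' facilities, 28 referring and 9 standalone facilities, with each
#' facility's readiness level consistent with its published readiness mark.
#'
#' The marginals do not determine the joint assignment; this particular
#' assignment is frozen here and guarded by [fixture_self_check()].
#'
#' @return a `facility_survey` data frame with 40 rows (39 assessed).
#' @export
build_study_fixture <- function() {
  dk <- c(sprintf("DK-HC-%02d", 1:6), sprintf("DK-HP-%02d", 1:7))
  kd <- c("KD-HC-01", sprintf("KD-HP-%02d", 1:25))
  ids <- c(dk, kd, "KD-HOSP-01")
  n <- length(ids)

  district <- c(rep("DAKAR_CENTRE", 13), rep("KOLDA", 27))
  ftype <- rep("HEALTH_POST", n)
  ftype[ids %in% sprintf("DK-HC-%02d", 1:6)] <- "HEALTH_CENTER_I"
  ftype[ids == "KD-HC-01"] <- "HEALTH_CENTER_II"
  ftype[ids == "KD-HOSP-01"] <- "HOSPITAL"
  assessed <- ids != "KD-HOSP-01"

  refers_to <- rep(NA_character_, n)
  refers_to[ids %in% c("DK-HC-04", "DK-HC-05", "DK-HC-06",
                       "DK-HP-05", "DK-HP-06", "DK-HP-07")] <- "DK-HC-01"
  refers_to[ids %in% sprintf("KD-HP-%02d", 1:3)] <- "KD-HOSP-01"
  refers_to[ids %in% sprintf("KD-HP-%02d", 4:22)] <- "KD-HC-01"

  # synthetic planar coordinates (meters): compact urban cluster, spread
  # rural district to the east
  set_xy <- function(k, x0, y0, dx, per_row) {
    i <- seq_len(k) - 1
    cbind(x0 + (i %% per_row) * dx, y0 + (i %/% per_row) * dx)
  }
  xy <- rbind(set_xy(13, 2000, 2000, 800, 4),
              set_xy(26, 3000, 2000, 5000, 5),
              c(24500, 23500))

  df <- data.frame(facility_id = ids, district = district,
                   facility_type = ftype,
                   x = xy[, 1], y = xy[, 2],
                   assessed = assessed, refers_to = refers_to,
                   stringsAsFactors = FALSE)

  # start from a fully-stocked assessed facility, then apply knockouts
  for (cl in c(.general_cols[1:4], .equip_cols)) df[[cl]] <- TRUE
  df$removal_days_per_week <- ifelse(grepl("HC", ids), 7L, 5L)
  df$n_trained_removal <- 2L
  df$n_trained_ultrasound <- 0L
  df$autoclave <- TRUE

  knock <- function(col, false_ids) {
    df[[col]][ids %in% false_ids] <<- FALSE
  }
  knock("syringes", c("DK-HP-01", "DK-HP-03", "KD-HP-19"))
  knock("local_anesthetic", c("DK-HP-04", "KD-HP-20", "KD-HP-21"))
  knock("sterile_band_aids", c("DK-HP-01", "DK-HP-03", "KD-HP-22"))
  knock("scalpel_with_blade", c("DK-HP-01", "DK-HP-03",
                                "KD-HP-20", "KD-HP-21"))
  knock("curved_forceps", c("DK-HP-01", "DK-HP-03"))
  knock("straight_forceps", c("DK-HP-04", "KD-HP-23"))
  # sterile dressing: one facility relies on the antiseptic+cotton branch
  knock("sterile_gauze", "DK-HP-02")
  knock("running_water", sprintf("KD-HP-%02d", 16:18))
  knock("vasectomy_forceps",
        c("DK-HC-01", "DK-HP-01", "DK-HP-03", "DK-HP-04", "DK-HP-06",
          "DK-HP-07", "KD-HC-01", sprintf("KD-HP-%02d", 16:25)))
  knock("sterile_towels",
        c("DK-HC-05", "DK-HP-03", "DK-HP-04", sprintf("KD-HP-%02d", 17:23)))
  knock("sterile_surgical_drape",
        c("DK-HC-02", "DK-HP-01", "DK-HP-02", "DK-HP-03", "DK-HP-04",
          "DK-HP-07", sprintf("KD-HP-%02d", 14:23), "KD-HP-25"))
  df$ultrasound_machine <- ids %in% c(sprintf("DK-HC-%02d", 1:5),
                                      "KD-HC-01", "KD-HP-01", "KD-HP-16")
  df$n_trained_ultrasound[ids %in% c(sprintf("DK-HC-%02d", 1:4),
                                     "KD-HC-01", "KD-HP-01",
                                     "KD-HP-24")] <- 1L
  # additional (reporting-only) indicators
  one_trained <- c(sprintf("DK-HP-%02d", 1:4), sprintf("KD-HP-%02d", 16:23))
  df$n_trained_removal[ids %in% one_trained] <- 1L
  knock("autoclave", c(sprintf("DK-HP-%02d", 1:4),
                       sprintf("KD-HP-%02d", 14:23)))

  # the unassessed hospital has no checklist data
  un <- !assessed
  for (cl in c(.general_cols, .staff_cols, .equip_cols, "autoclave")) {
    df[[cl]][un] <- NA
  }
  facility_survey(df)
}

#' Verify the fixture against its published aggregate surface
#'
#' Re-runs the readiness and referral pipeline on [build_study_fixture()]
#' and checks every frozen aggregate: the district and total percentages
#' for each component and level, the facility-type mix, the referral
#' network sizes and role counts, and the receiving/standalone readiness
#' counts. Errors on the first mismatch; returns the fixture invisibly.
#'
#' @return the fixture, invisibly.
#' @export
fixture_self_check <- function() {
  f <- build_study_fixture()
  s <- summarize_readiness(f)
  expect <- function(row, want) {
    got <- unlist(s[s$row == row, c("DAKAR_CENTRE", "KOLDA", "Total")])
    if (!all(got == want)) {
      stop_ra(sprintf("fixture self-check failed for '%s': got %s, want %s",
                      row, paste(got, collapse = "/"),
                      paste(want, collapse = "/")), "ra_fixture_error")
    }
  }
  expect("Regular removals", c(77, 69, 72))
  expect("General service readiness", c(100, 88, 92))
  expect("Running water", c(100, 88, 92))
  expect("Human resources: 1+ staff trained in implant removal",
         c(100, 100, 100))
  expect("Minimum equipment (regular)", c(77, 81, 79))
  expect("Syringes", c(85, 96, 92))
  expect("Local anesthetic", c(92, 92, 92))
  expect("Sterile band aids", c(85, 96, 92))
  expect("Scalpel with blade", c(85, 92, 90))
  expect("Curved forceps", c(85, 100, 95))
  expect("Straight forceps", c(92, 96, 95))
  expect("Sterile gauze, or antiseptic and cotton balls", c(100, 100, 100))
  expect("Difficult removals", c(15, 4, 8))
  expect("Human resources: 1+ staff trained to use ultrasound", c(31, 12, 18))
  expect("Minimum equipment (difficult)", c(15, 4, 8))
  expect("Modified vasectomy forceps", c(54, 58, 56))
  expect("Ultrasound", c(38, 12, 21))
  expect("Sterile towels", c(77, 73, 74))
  expect("Examination table", c(100, 100, 100))
  expect("Sterile dry surgical drape", c(54, 58, 56))

  nets <- build_networks(f)
  if (!identical(sort(nets$networks$size, decreasing = TRUE), c(20L, 7L, 4L))) {
    stop_ra("fixture self-check failed: network sizes", "ra_fixture_error")
  }
  rc <- table(nets$roles$role)
  if (rc[["REFERRING"]] != 28 || rc[["STANDALONE"]] != 9 ||
      rc[["RECEIVING"]] != 3) {
    stop_ra("fixture self-check failed: role counts", "ra_fixture_error")
  }
  rat <- assess_rationality(nets, classify_readiness(f[f$assessed, ]), f)
  e <- rat$endpoints
  if (e[["n_assessed"]] != 11 || e[["regular_ready"]] != 7 ||
      e[["difficult_ready"]] != 1) {
    stop_ra("fixture self-check failed: rationality counts",
            "ra_fixture_error")
  }
  tt <- table(f$facility_type[f$assessed])
  if (tt[["HEALTH_POST"]] != 32 || tt[["HEALTH_CENTER_I"]] != 6 ||
      tt[["HEALTH_CENTER_II"]] != 1) {
    stop_ra("fixture self-check failed: facility types", "ra_fixture_error")
  }
  ai <- additional_indicators(f)
  if (ai[["autoclave"]] != 64 || ai[["two_plus_removal_trained"]] != 69) {
    stop_ra("fixture self-check failed: additional indicators",
            "ra_fixture_error")
  }
  invisible(f)
}
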