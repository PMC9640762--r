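test_that("general service readiness is the published conjunction", {
  ok <- make_facility()
  expect_true(general_service_ready(make_survey(ok)))
  expect_false(general_service_ready(make_survey(
    make_facility(running_water = FALSE))))
  expect_false(general_service_ready(make_survey(
    make_facility(removal_days_per_week = 4L))))
  expect_true(general_service_ready(make_survey(
    make_facility(removal_days_per_week = 7L))))
})

test_that("equipment readiness honors the sterile-dressing alternative", {
  # gauze absent but antiseptic + cotton present still passes regular
  f <- make_survey(make_facility(sterile_gauze = FALSE))
  expect_true(equipment_ready(f, "REGULAR"))
  # with cotton also absent the alternative collapses
  f2 <- make_survey(make_facility(sterile_gauze = FALSE,
                                  cotton_balls = FALSE))
  expect_false(equipment_ready(f2, "REGULAR"))
  # gauze alone satisfies the default reading
  f3 <- make_survey(make_facility(antiseptic = FALSE, cotton_balls = FALSE))
  expect_true(equipment_ready(f3, "REGULAR"))
  # ... but not the alternative (antiseptic AND (cotton OR gauze)) reading
  alt <- readiness_criteria("antiseptic_and_cotton_or_gauze")
  expect_false(equipment_ready(f3, "REGULAR", alt))
  expect_true(equipment_ready(f, "REGULAR", alt))
})

test_that("difficult equipment requires the full additional block", {
  f <- make_survey(make_facility(ultrasound_machine = FALSE))
  expect_true(equipment_ready(f, "REGULAR"))
  expect_false(equipment_ready(f, "DIFFICULT"))
  full <- make_survey(make_facility())
  expect_true(equipment_ready(full, "DIFFICULT"))
  # the equipment tray is part of the difficult block
  tray <- make_survey(make_facility(sterile_equipment_tray = FALSE))
  expect_false(equipment_ready(tray, "DIFFICULT"))
})

test_that("human resources thresholds on trained staff counts", {
  cases <- list(list(1L, 0L, TRUE, FALSE), list(0L, 1L, FALSE, FALSE),
                list(2L, 3L, TRUE, TRUE))
  for (cs in cases) {
    f <- make_survey(make_facility(n_trained_removal = cs[[1]],
                                   n_trained_ultrasound = cs[[2]]))
    expect_equal(human_resources_ready(f, "REGULAR"), cs[[3]])
    expect_equal(human_resources_ready(f, "DIFFICULT"), cs[[4]])
  }
})

test_that("classification assigns the highest level whose criteria hold", {
  expect_equal(classify_readiness(make_survey(make_facility()))$level,
               "DIFFICULT")
  expect_equal(classify_readiness(make_survey(
    make_facility(n_trained_ultrasound = 0L)))$level, "REGULAR")
  expect_equal(classify_readiness(make_survey(
    make_facility(scalpel_with_blade = FALSE)))$level, "NOT_READY")
})

test_that("readiness of an unassessed facility is not assessable", {
  f <- as.data.frame(build_study_fixture())
  un <- facility_survey(f[f$facility_id == "KD-HOSP-01", ])
  expect_error(classify_readiness(un), class = "ra_not_assessable_error")
  expect_error(general_service_ready(un), class = "ra_not_assessable_error")
})

test_that("classifier agrees with a literal brute-force evaluator", {
  set.seed(42)
  for (rep in 1:8) {
    recs <- lapply(sprintf("R-%02d", 1:25), random_facility)
    f <- do.call(make_survey, recs)
    got <- classify_readiness(f)
    want <- vapply(seq_len(nrow(f)),
                   function(i) oracle_level(f[i, ]), character(1))
    expect_identical(got$level, want)
    # nesting: every DIFFICULT facility also satisfies the regular criteria
    dif <- got$level == "DIFFICULT"
    expect_true(all(got$general_ok[dif] & got$hr_regular_ok[dif] &
                      got$equip_regular_ok[dif]))
  }
})

test_that("turning any checklist item on never lowers the level", {
  rank <- c(NOT_READY = 0, REGULAR = 1, DIFFICULT = 2)
  flags <- c("running_water", "decontamination_buckets", "safety_boxes",
             "soap", "syringes", "local_anesthetic", "sterile_band_aids",
             "scalpel_with_blade", "curved_forceps", "straight_forceps",
             "antiseptic", "cotton_balls", "sterile_gauze",
             "vasectomy_forceps", "ultrasound_machine", "sterile_towels",
             "examination_table", "sterile_surgical_drape",
             "sterile_equipment_tray")
  set.seed(7)
  for (rep in 1:40) {
    f <- make_survey(random_facility("X-01"))
    base <- rank[[classify_readiness(f)$level]]
    off <- flags[!vapply(flags, function(cl) f[[cl]][1], logical(1))]
    for (cl in off) {
      g <- f
      g[[cl]][1] <- TRUE
      expect_gte(rank[[classify_readiness(g)$level]], base)
    }
  }
})

test_that("summary percentages behave as a rounded partition", {
  # a single fully-ready facility yields 100 in every row
  s1 <- summarize_readiness(make_survey(make_facility()))
  expect_true(all(s1$Total == 100))

  # mutually exclusive level shares add to 100 within rounding error
  set.seed(11)
  for (rep in 1:10) {
    recs <- lapply(sprintf("R-%02d", 1:17), random_facility)
    f <- do.call(make_survey, recs)
    r <- classify_readiness(f)
    shares <- pct <- vapply(c("NOT_READY", "REGULAR", "DIFFICULT"),
                            function(lv) round_half_up(100 * mean(r$level == lv)),
                            numeric(1))
    expect_lte(abs(sum(shares) - 100), 1)
  }

  expect_error(summarize_readiness(
    facility_survey(make_facility()[0, ])), class = "ra_empty_input_error")
})

test_that("rounding is half away from zero", {
  expect_equal(round_half_up(100 * 23 / 26), 88)
  expect_equal(round_half_up(100 * 31 / 39), 79)
  expect_equal(round_half_up(100 * 8 / 39), 21)
  expect_equal(round_half_up(88.5), 89)
  expect_equal(round_half_up(0.15, 1), 0.2)
})

test_that("criteria tables round-trip through JSON", {
  path <- tempfile(fileext = ".json")
  crit <- readiness_criteria("antiseptic_and_cotton_or_gauze")
  write_criteria(crit, path)
  back <- read_criteria(path)
  expect_equal(back$equipment_any_of, crit$equipment_any_of)
  expect_equal(back$min_days_per_week, crit$min_days_per_week)
  unlink(path)
})

test_that("additional indicators are reported but never scored", {
  f <- make_survey(make_facility(autoclave = FALSE, n_trained_removal = 1L))
  expect_equal(classify_readiness(f)$level, "DIFFICULT")
  ai <- additional_indicators(f)
  expect_equal(unname(ai["autoclave"]), 0)
  expect_equal(unname(ai["two_plus_removal_trained"]), 0)
})
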