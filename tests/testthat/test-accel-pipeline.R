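test_that("MAD-to-MET conversion has the resting floor and is monotone", {
  expect_equal(mad_to_met(0), 1.0)
  grid <- seq(0, 1, by = 0.01)
  met <- mad_to_met(grid)
  expect_true(all(diff(met) >= 0))
  expect_gte(min(met), 1.0)
  # a calibration mapping mad 0.25 g to VO2 21 mL/kg/min gives 21/3.5 = 6 MET
  cal <- met_calibration(mad_knots = c(0, 0.25), vo2_knots = c(3.5, 21))
  expect_equal(mad_to_met(0.25, cal), 6.0)
  expect_error(mad_to_met(-0.1), "non-negative")
  expect_error(met_calibration(c(0, 0.2), c(10, 3)), "non-decreasing")
})

test_that("posture classification honours the MET gate and APE bands", {
  # < 11.6 deg standing; 11.6-72.0 sitting; > 72.0 lying; MET >= 1.5 active
  expect_equal(as.character(classify_posture(1.2, 5)), "standing")
  expect_equal(as.character(classify_posture(1.2, 80)), "lying")
  expect_equal(as.character(classify_posture(1.6, 80)), "active")
  # band edges: 11.6 goes to sitting, 72.0 stays sitting, just above is lying
  expect_equal(as.character(classify_posture(c(1.2, 1.2, 1.2, 1.2),
                                             c(11.59, 11.6, 72.0, 72.01))),
               c("standing", "sitting", "sitting", "lying"))
  # unknown angle at low MET is unknown, at high MET still active
  expect_equal(as.character(classify_posture(c(1.2, 3), c(NA, NA))),
               c("unknown", "active"))
  expect_error(classify_posture(1.2, 200), "0, 180")
})

test_that("intensity classification uses the 1.5/3.0/6.0 MET cut-points", {
  met <- c(6.0, 5.99, 3.0, 2.99, 1.49, 1.49, 1.49)
  posture <- c("active", "active", "active", "standing", "sitting", "lying",
               "standing")
  got <- as.character(classify_intensity(met, posture))
  expect_equal(got, c("VPA", "MPA", "MPA", "light", "SB", "SB", "light"))
})

test_that("posture and intensity assign every wear epoch exactly one class", {
  set.seed(13)
  met <- runif(500, 1, 8)
  ape <- runif(500, 0, 180)
  posture <- classify_posture(met, ape)
  intensity <- classify_intensity(met, posture)
  expect_false(any(is.na(posture)))
  expect_false(any(is.na(intensity)))
  # the SB flag is exactly (met < 1.5 and sitting/lying)
  expect_equal(intensity == "SB",
               met < 1.5 & as.character(posture) %in% c("sitting", "lying"))
})

test_that("non-wear detection flags sustained stillness runs", {
  active_day <- rep(0.1, 1000)
  expect_true(all(detect_nonwear(active_day)))

  # 90 still minutes (900 epochs) inside an active day
  mad <- c(rep(0.1, 200), rep(0, 900), rep(0.1, 200))
  wear <- detect_nonwear(mad, window_min = 60)
  expect_equal(which(!wear), 201:1100)

  # run shorter than the window stays wear
  mad2 <- c(rep(0.1, 200), rep(0, 400), rep(0.1, 200))
  expect_true(all(detect_nonwear(mad2, window_min = 60)))

  # threshold-straddling pattern matches a brute-force run scan
  set.seed(5)
  mad3 <- ifelse(runif(3000) < 0.6, 0, 0.05)
  got <- detect_nonwear(mad3, window_min = 10, mad_threshold_g = 0.01)
  r <- rle(mad3 < 0.01)
  expected <- !inverse.rle(list(values = r$values & r$lengths >= 100,
                                lengths = r$lengths))
  expect_equal(got, expected)
})

test_that("day summaries count minutes and apply the 600-min validity rule", {
  # exactly 600 awake-wear minutes (6000 epochs) -> valid
  d600 <- day_of(n_sb = 3000, n_light = 2900, n_mpa = 100)
  expect_true(d600$valid)
  expect_equal(d600$awake_wear_min, 600)
  expect_equal(d600$mpa_min, 10)           # 100 epochs x 6 s
  expect_equal(d600$sb_min, 300)

  # 599 minutes -> invalid
  d599 <- day_of(n_sb = 5990)
  expect_false(d599$valid)

  # weekend flag follows the calendar; 2024-06-08 is a Saturday
  sat <- day_of(n_sb = 100, date = as.Date("2024-06-08"))
  mon <- day_of(n_sb = 100, date = as.Date("2024-06-03"))
  expect_true(sat$is_weekend)
  expect_false(mon$is_weekend)

  # minutes partition awake wear time
  expect_equal(d600$sb_min + d600$light_min + d600$mpa_min + d600$vpa_min,
               d600$awake_wear_min)

  empty <- summarise_day(data.frame())
  expect_false(empty$valid)
  expect_equal(empty$awake_wear_min, 0)
})

test_that("week summaries enforce 4 valid days incl. a weekend day", {
  wk <- function(dates, mpa_epochs) {
    do.call(rbind, Map(function(d, m) day_of(n_sb = 6000, n_mpa = m,
                                             date = d),
                       dates, mpa_epochs))
  }
  # 5 valid weekdays, no weekend -> excluded
  wd5 <- wk(as.Date("2024-06-03") + 0:4, rep(300, 5))
  s <- summarise_week(wd5)
  expect_false(s$included)
  expect_equal(s$exclusion_reason, "no_weekend_day")

  # 7 uniform valid days with 30 MPA min -> 210 min/week
  full <- wk(as.Date("2024-06-03") + 0:6, rep(300, 7))
  s7 <- summarise_week(full)
  expect_true(s7$included)
  expect_equal(s7$mpa_min_per_week, 210)

  # 3 weekdays at 30 min + 1 weekend day at 60 min:
  # weekly = 7 x (5/7 x 30 + 2/7 x 60) = 270
  mix <- wk(as.Date(c("2024-06-03", "2024-06-04", "2024-06-05",
                      "2024-06-08")), c(300, 300, 300, 600))
  expect_equal(summarise_week(mix)$mpa_min_per_week, 270)

  # 3 valid days only -> excluded for too few days
  few <- wk(as.Date("2024-06-03") + c(0, 1, 5), rep(300, 3))
  expect_equal(summarise_week(few)$exclusion_reason, "too_few_valid_days")
})

test_that("process_epochs reduces a constructed week to the expected summary", {
  # two participants, 7 days each of 720 awake-wear minutes:
  # 360 min SB, ~320 light, 30 MPA, 10 VPA per day (as 6-s epochs)
  mk_day <- function(date, id) {
    cls <- c(rep("light", 1000), rep("sb", 3600), rep("light", 1000),
             rep("mpa", 300), rep("light", 1000), rep("vpa", 100),
             rep("light", 200))
    epochs_from_classes(cls, date = date, id = id)
  }
  eps <- do.call(rbind, lapply(as.Date("2024-06-03") + 0:6, function(d) {
    rbind(mk_day(d, "A"), mk_day(d, "B"))
  }))
  out <- process_epochs(eps)
  expect_equal(nrow(out$participants), 2)
  expect_equal(out$participants$n_valid_days, c(7, 7))
  expect_true(all(out$participants$included))
  # smoothing blurs block edges by at most a few epochs
  expect_equal(out$participants$mvpa_min_per_week, c(280, 280),
               tolerance = 0.05)
  expect_equal(out$participants$sb_min_per_day, c(360, 360),
               tolerance = 0.02)
  expect_equal(out$participants$mvpa_min_per_week,
               out$participants$mpa_min_per_week +
                 out$participants$vpa_min_per_week)
})
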