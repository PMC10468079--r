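#' MAD-to-VO2 calibration object
#'
#' The MAD intensity metric is converted to energy expenditure through a
#' monotone non-decreasing mapping from MAD (g) to estimated oxygen uptake
#' (mL/kg/min); METs are then VO2 / 3.5. The mapping is device- and
#' wear-site-specific and pluggable. The default is a piecewise-linear map
#' anchored at widely used hip-worn MAD intensity cut-points: 0 g at the
#' resting floor (3.5 mL/kg/min), 0.091 g at 3 MET (10.5 mL/kg/min) and
#' 0.414 g at 6 MET (21 mL/kg/min), extrapolating with the last slope.
#'
#' @param mad_knots,vo2_knots numeric vectors of equal length (>= 2) giving
#'   the MAD (g) and VO2 (mL/kg/min) coordinates of the piecewise-linear
#'   calibration; both must be non-decreasing and start at mad = 0.
#' @return An object of class `met_calibration`.
#' @export
met_calibration <- function(mad_knots = c(0, 0.091, 0.414),
                            vo2_knots = c(3.5, 10.5, 21)) {
  if (length(mad_knots) != length(vo2_knots) || length(mad_knots) < 2L) {
    stop_input("calibration needs >= 2 matching (mad, vo2) knots")
  }
  if (mad_knots[1] != 0) stop_input("calibration must start at mad = 0")
  if (is.unsorted(mad_knots, strictly = TRUE)) {
    stop_input("mad_knots must be strictly increasing")
  }
  if (is.unsorted(vo2_knots)) {
    stop_input("vo2_knots must be non-decreasing (monotone calibration)")
  }
  structure(list(mad = mad_knots, vo2 = vo2_knots),
            class = "met_calibration")
}

#' @export
print.met_calibration <- function(x, ...) {
  cat("<met_calibration> piecewise-linear MAD (g) -> VO2 (mL/kg/min)\n")
  print(data.frame(mad_g = x$mad, vo2 = x$vo2, met = x$vo2 / 3.5),
        row.names = FALSE)
  invisible(x)
}

#' Convert MAD to METs
#'
#' VO2 is interpolated from the calibration (linear extrapolation beyond the
#' last knot) and divided by 3.5 mL/kg/min (1 MET); results are floored at
#' 1.0 MET, the resting level.
#'
#' @param mad_g non-negative MAD values in g.
#' @param calibration a [met_calibration()] object.
#' @return MET values, same length as `mad_g`; monotone non-decreasing in
#'   `mad_g`, never below 1.0.
#' @export
mad_to_met <- function(mad_g, calibration = met_calibration()) {
  stopifnot(inherits(calibration, "met_calibration"))
  if (any(is.na(mad_g)) || any(mad_g < 0)) {
    stop_input("mad_g must be non-negative and non-missing")
  }
  k <- length(calibration$mad)
  slope_end <- if (k > 1) {
    (calibration$vo2[k] - calibration$vo2[k - 1]) /
      (calibration$mad[k] - calibration$mad[k - 1])
  } else 0
  vo2 <- stats::approx(calibration$mad, calibration$vo2, xout = pmin(mad_g, calibration$mad[k]),
                       rule = 2)$y
  over <- mad_g > calibration$mad[k]
  vo2[over] <- calibration$vo2[k] + slope_end * (mad_g[over] - calibration$mad[k])
  pmax(1.0, vo2 / 3.5)
}

#' Classify posture from smoothed MET and APE
#'
#' Epochs with smoothed MET >= 1.5 are `"active"`. Below that, posture is
#' read off the smoothed posture angle: standing below 11.6 degrees, sitting
#' from 11.6 to 72.0 degrees (inclusive), lying above 72.0 degrees. A missing
#' angle at low MET gives `"unknown"`, which counts as neither sedentary nor
#' standing time.
#'
#' @param met_smoothed numeric vector of smoothed MET values.
#' @param ape_smoothed numeric vector of smoothed posture angles in degrees
#'   (`NA` allowed).
#' @param standing_max,sitting_max APE band edges in degrees (defaults 11.6
#'   and 72.0).
#' @return Factor with levels standing, sitting, lying, active, unknown.
#' @export
classify_posture <- function(met_smoothed, ape_smoothed,
                             standing_max = 11.6, sitting_max = 72.0) {
  n <- length(met_smoothed)
  if (length(ape_smoothed) != n) stop_input("met and ape lengths differ")
  if (any(ape_smoothed < 0 | ape_smoothed > 180, na.rm = TRUE)) {
    stop_input("ape_smoothed must lie in [0, 180] degrees")
  }
  out <- rep("active", n)
  low <- !is.na(met_smoothed) & met_smoothed < 1.5
  out[low & is.na(ape_smoothed)] <- "unknown"
  known <- low & !is.na(ape_smoothed)
  out[known & ape_smoothed < standing_max] <- "standing"
  out[known & ape_smoothed >= standing_max & ape_smoothed <= sitting_max] <- "sitting"
  out[known & ape_smoothed > sitting_max] <- "lying"
  factor(out, levels = c("standing", "sitting", "lying", "active", "unknown"))
}

#' Classify activity intensity from smoothed MET and posture
#'
#' Cut-points: VPA at MET >= 6.0, MPA at 3.0 <= MET < 6.0, sedentary
#' behaviour (SB) at MET < 1.5 with sitting or lying posture, light
#' otherwise.
#'
#' @param met_smoothed numeric vector of smoothed MET values.
#' @param posture factor/character from [classify_posture()].
#' @param sb_max,mpa_min,vpa_min MET cut-points (defaults 1.5, 3.0, 6.0).
#' @return Factor with levels SB, light, MPA, VPA.
#' @export
classify_intensity <- function(met_smoothed, posture,
                               sb_max = 1.5, mpa_min = 3.0, vpa_min = 6.0) {
  n <- length(met_smoothed)
  if (length(posture) != n) stop_input("met and posture lengths differ")
  posture <- as.character(posture)
  out <- rep("light", n)
  out[met_smoothed >= vpa_min] <- "VPA"
  out[met_smoothed >= mpa_min & met_smoothed < vpa_min] <- "MPA"
  out[met_smoothed < sb_max & posture %in% c("sitting", "lying")] <- "SB"
  factor(out, levels = c("SB", "light", "MPA", "VPA"))
}

#' Flag non-wear epochs from sustained zero movement
#'
#' Runs of at least `window_min` minutes with MAD below `mad_threshold_g` are
#' flagged as non-wear.
#'
#' @param mad_g per-epoch MAD values in g.
#' @param window_min minimum run length in minutes (default 60).
#' @param mad_threshold_g stillness threshold in g (default 0.0067).
#' @param epoch_len_s epoch length in seconds (default 6).
#' @return Logical vector: TRUE where the device is judged worn.
#' @export
detect_nonwear <- function(mad_g, window_min = 60, mad_threshold_g = 0.0067,
                           epoch_len_s = 6) {
  check_number(window_min, "window_min", lower = epoch_len_s / 60)
  check_number(mad_threshold_g, "mad_threshold_g", lower = 0)
  still <- mad_g < mad_threshold_g
  r <- rle(still)
  min_epochs <- ceiling(window_min * 60 / epoch_len_s)
  nonwear_run <- r$values & r$lengths >= min_epochs
  !inverse.rle(list(values = nonwear_run, lengths = r$lengths))
}

#' Summarise one participant-day of classified epochs
#'
#' Minutes per intensity class are counted over awake wear epochs
#' (epochs x epoch length / 60). A day is valid when awake wear time reaches
#' `valid_day_min` minutes (default 600). The weekend flag comes from the
#' calendar date (Saturday/Sunday).
#'
#' @param epochs data frame for a single participant-day with columns
#'   `epoch_start` (POSIXct or Date-time string), `intensity`, `wear`,
#'   `awake`.
#' @param valid_day_min valid-day wear threshold in minutes (default 600).
#' @param epoch_len_s epoch length in seconds (default 6).
#' @return One-row data frame: `date`, `awake_wear_min`, `sb_min`,
#'   `light_min`, `mpa_min`, `vpa_min`, `is_weekend`, `valid`.
#' @export
summarise_day <- function(epochs, valid_day_min = 600, epoch_len_s = 6) {
  if (nrow(epochs) == 0L) {
    return(data.frame(date = as.Date(NA), awake_wear_min = 0, sb_min = 0,
                      light_min = 0, mpa_min = 0, vpa_min = 0,
                      is_weekend = FALSE, valid = FALSE))
  }
  ts <- as.POSIXct(epochs$epoch_start, tz = "UTC")
  date <- as.Date(ts[1])
  use <- epochs$wear & epochs$awake
  mins <- function(cls) sum(use & epochs$intensity == cls) * epoch_len_s / 60
  awake_wear <- sum(use) * epoch_len_s / 60
  data.frame(
    date = date,
    awake_wear_min = awake_wear,
    sb_min = mins("SB"),
    light_min = mins("light"),
    mpa_min = mins("MPA"),
    vpa_min = mins("VPA"),
    is_weekend = format(date, "%u") %in% c("6", "7"),
    valid = awake_wear >= valid_day_min
  )
}

#' Summarise a participant's week of day summaries
#'
#' A participant is included when there are at least `min_valid_days` valid
#' days of which at least one falls on a weekend. Daily sedentary minutes are
#' averaged over valid days; weekly activity minutes are 7 x the 5:2
#' weekday:weekend weighted mean of daily minutes over valid days (falling
#' back to the unweighted mean when one stratum is empty), so that the
#' weekend day the inclusion rule demands keeps its calendar weight.
#'
#' @param days data frame of [summarise_day()] rows for one participant.
#' @param min_valid_days minimum number of valid days (default 4).
#' @param require_weekend require at least one valid weekend day
#'   (default TRUE).
#' @return One-row data frame with `sb_min_per_day`, `mpa_min_per_week`,
#'   `vpa_min_per_week`, `mvpa_min_per_week`, `n_valid_days`,
#'   `has_weekend_day`, `included`, `exclusion_reason`.
#' @export
summarise_week <- function(days, min_valid_days = 4, require_weekend = TRUE) {
  stopifnot(nrow(days) >= 1L)
  v <- days[days$valid, , drop = FALSE]
  n_valid <- nrow(v)
  has_weekend <- any(v$is_weekend)
  included <- n_valid >= min_valid_days && (!require_weekend || has_weekend)
  reason <- if (included) NA_character_
            else if (n_valid < min_valid_days) "too_few_valid_days"
            else "no_weekend_day"
  weekly <- function(col) {
    if (n_valid == 0L) return(NA_real_)
    wd <- v[[col]][!v$is_weekend]
    we <- v[[col]][v$is_weekend]
    if (length(wd) == 0L || length(we) == 0L) {
      7 * mean(v[[col]])
    } else {
      7 * (5 / 7 * mean(wd) + 2 / 7 * mean(we))
    }
  }
  mpa <- weekly("mpa_min")
  vpa <- weekly("vpa_min")
  data.frame(
    sb_min_per_day = if (n_valid > 0) mean(v$sb_min) else NA_real_,
    mpa_min_per_week = mpa,
    vpa_min_per_week = vpa,
    mvpa_min_per_week = mpa + vpa,
    n_valid_days = n_valid,
    has_weekend_day = has_weekend,
    included = included,
    exclusion_reason = reason,
    stringsAsFactors = FALSE
  )
}

#' Reduce an epoch table to per-participant weekly summaries
#'
#' The cohort-scale entry point of the accelerometer pipeline. Accepts a long
#' epoch table (one row per 6-s epoch) holding either a raw `met` column (and
#' `ape_deg` or `posture`) or pre-classified columns. MET values are smoothed
#' with an exponential moving average (default time constant 20 s), posture
#' angles with a one-minute EMA, then epochs are classified, days summarised
#' and weeks reduced.
#'
#' @param epochs data frame with columns `participant_id`, `epoch_start`,
#'   `met` (raw per-epoch MET), `wear`, `awake`, and either `posture` or
#'   `ape_deg`.
#' @param met_tc_s MET smoothing time constant in seconds (default 20).
#' @param ape_tc_s posture-angle smoothing time constant in seconds
#'   (default 60, i.e. a one-minute EMA).
#' @param valid_day_min,min_valid_days,require_weekend inclusion rules; see
#'   [summarise_day()] and [summarise_week()].
#' @param epoch_len_s epoch length in seconds (default 6).
#' @return List with `days` (per participant-day summaries) and
#'   `participants` (one row per participant, `participant_id` first).
#' @export
process_epochs <- function(epochs, met_tc_s = 20, ape_tc_s = 60,
                           valid_day_min = 600, min_valid_days = 4,
                           require_weekend = TRUE, epoch_len_s = 6) {
  need <- c("participant_id", "epoch_start", "met", "wear", "awake")
  miss <- setdiff(need, names(epochs))
  if (length(miss)) stop_input("epoch table lacks columns: %s",
                               paste(miss, collapse = ", "))
  if (!("posture" %in% names(epochs)) && !("ape_deg" %in% names(epochs))) {
    stop_input("epoch table needs a `posture` or `ape_deg` column")
  }
  split_idx <- split(seq_len(nrow(epochs)), epochs$participant_id)
  day_list <- list()
  part_list <- list()
  for (pid in names(split_idx)) {
    e <- epochs[split_idx[[pid]], , drop = FALSE]
    e <- e[order(as.POSIXct(e$epoch_start, tz = "UTC")), , drop = FALSE]
    met_s <- smooth_ema(e$met, time_constant_s = met_tc_s,
                        epoch_len_s = epoch_len_s)
    if ("posture" %in% names(e)) {
      posture <- as.character(e$posture)
      # honour the MET gate even for supplied postures
      posture[met_s >= 1.5] <- "active"
    } else {
      ape_s <- smooth_ema(e$ape_deg, time_constant_s = ape_tc_s,
                          epoch_len_s = epoch_len_s)
      posture <- as.character(classify_posture(met_s, ape_s))
    }
    e$intensity <- classify_intensity(met_s, posture)
    dts <- as.Date(as.POSIXct(e$epoch_start, tz = "UTC"))
    days <- do.call(rbind, lapply(split(e, dts), summarise_day,
                                  valid_day_min = valid_day_min,
                                  epoch_len_s = epoch_len_s))
    days <- cbind(participant_id = pid, days, row.names = NULL)
    wk <- summarise_week(days, min_valid_days = min_valid_days,
                         require_weekend = require_weekend)
    day_list[[pid]] <- days
    part_list[[pid]] <- cbind(participant_id = pid, wk, row.names = NULL)
  }
  list(days = do.call(rbind, c(day_list, list(make.row.names = FALSE))),
       participants = do.call(rbind, c(part_list, list(make.row.names = FALSE))))
}
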