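#' Generate a synthetic cohort of true-behaviour profiles
#'
#' Draws participants with demographics, a latent cardiorespiratory fitness
#' z-score, six-minute-walk distances tied to latent fitness, and true weekly
#' activity / daily sedentary behaviour. The fitness-group label used by the
#' reporting model is the tercile of latent fitness (independent of the
#' analysis-side 6MWT grouping, so the grouping stage can be validated
#' against generation).
#'
#' @param config a [cohort_config()].
#' @return Data frame with one row per participant: `participant_id`, `sex`,
#'   `age`, `height_cm`, `weight_kg`, `waist_cm`, `latent_fitness`,
#'   `fitness_group`, `sixmwt_m`, `true_sb_min_per_day`,
#'   `true_mpa_min_per_week`, `true_vpa_min_per_week`,
#'   `true_mvpa_min_per_week`. Deterministic for a fixed `config$seed`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_participants
  with_seed(config$seed, {
    id <- sprintf("P%04d", seq_len(n))
    sex <- ifelse(stats::runif(n) < config$sex_ratio, "male", "female")
    age <- stats::rnorm(n, config$age_mean, config$age_sd)
    age <- pmin(pmax(age, config$age_range[1]), config$age_range[2])
    z <- stats::rnorm(n, 0, config$fitness_latent_sd)
    grp <- rank_terciles(z, id)
    height <- ifelse(sex == "male", stats::rnorm(n, 178, 7),
                     stats::rnorm(n, 165, 6.5))
    bmi <- pmin(pmax(stats::rnorm(n, 25.5 - 1.2 * z, 3.5), 17), 45)
    weight <- bmi * (height / 100)^2
    waist <- pmax(55, 2.4 * bmi + ifelse(sex == "male", 34, 26) +
                    stats::rnorm(n, 0, 5))
    sixmwt <- pmax(150, config$sixmwt_base + config$sixmwt_fitness_slope * z +
                     stats::rnorm(n, 0, config$sixmwt_resid_sd))
    mvpa_mean <- config$true_mvpa_mean_by_fitness[grp]
    mvpa <- mvpa_mean * rlnorm_mean1(n, config$true_mvpa_cv)
    share_mean <- pmax(config$true_vpa_share_by_fitness[grp], 1e-6)
    vpa_share <- stats::rbeta(n, share_mean * 30, (1 - share_mean) * 30)
    vpa <- mvpa * vpa_share
    sb <- pmin(pmax(stats::rnorm(n, config$true_sb_mean, config$true_sb_sd),
                    60), 900)
    data.frame(
      participant_id = id, sex = sex, age = age,
      height_cm = height, weight_kg = weight, waist_cm = waist,
      latent_fitness = z,
      fitness_group = factor(grp, levels = FITNESS_LEVELS),
      sixmwt_m = sixmwt,
      true_sb_min_per_day = sb,
      true_mpa_min_per_week = mvpa - vpa,
      true_vpa_min_per_week = vpa,
      true_mvpa_min_per_week = mvpa,
      stringsAsFactors = FALSE
    )
  })
}

# split values into low/intermediate/high terciles by ascending value, ties
# broken by id order, cut ranks ceiling(n/3) and ceiling(2n/3)
rank_terciles <- function(values, ids) {
  n <- length(values)
  ord <- order(values, ids)
  cut1 <- ceiling(n / 3)
  cut2 <- ceiling(2 * n / 3)
  grp <- character(n)
  grp[ord[seq_len(cut1)]] <- "low"
  grp[ord[seq(cut1 + 1, cut2)]] <- "intermediate"
  grp[ord[seq(cut2 + 1, n)]] <- "high"
  grp
}

#' Simulate accelerometer-derived weekly summaries directly from truth
#'
#' Cohort-scale shortcut for the device arm of the study: weekly summaries
#' are the true values perturbed by small mean-one lognormal measurement
#' noise, standing in for a full week of epoch-level synthesis plus pipeline
#' reduction (which [generate_epoch_series()] plus [process_epochs()]
#' provide at bout scale).
#'
#' @param profiles output of [generate_cohort()].
#' @param seed integer seed.
#' @param cv_pa,cv_sb coefficients of variation of device measurement noise
#'   for weekly activity and daily sedentary minutes.
#' @return Data frame shaped like the `participants` element of
#'   [process_epochs()].
#' @export
simulate_device_summaries <- function(profiles, seed = 1L, cv_pa = 0.08,
                                      cv_sb = 0.05) {
  n <- nrow(profiles)
  with_seed(seed, {
    mpa <- profiles$true_mpa_min_per_week * rlnorm_mean1(n, cv_pa)
    vpa <- profiles$true_vpa_min_per_week * rlnorm_mean1(n, cv_pa)
    data.frame(
      participant_id = profiles$participant_id,
      sb_min_per_day = profiles$true_sb_min_per_day * rlnorm_mean1(n, cv_sb),
      mpa_min_per_week = mpa,
      vpa_min_per_week = vpa,
      mvpa_min_per_week = mpa + vpa,
      n_valid_days = 7L, has_weekend_day = TRUE, included = TRUE,
      stringsAsFactors = FALSE
    )
  })
}

#' Generate an epoch-level week for one participant
#'
#' Builds a per-6-s-epoch MET/posture series with realistic day structure:
#' sleep from 23:00 to 07:00, and an awake day assembled from sedentary,
#' light, moderate and vigorous blocks whose totals match the participant's
#' true behaviour (weekly activity allocated multinomially across days;
#' daily sedentary time jittered slightly). Activity blocks are always
#' buffered by light-activity blocks, as bouts in free-living data are.
#'
#' @param profile one-row data frame (a [generate_cohort()] row).
#' @param days number of days (>= 1, default 7), starting on a Monday.
#' @param seed integer seed.
#' @param nonwear_days integer day indices whose epochs are flagged as not
#'   worn (injectable non-wear gaps).
#' @param start_date first (Monday) calendar date of wear.
#' @return Data frame with columns `participant_id`, `epoch_start`
#'   (POSIXct, UTC), `met`, `posture`, `wear`, `awake`; directly consumable
#'   by [process_epochs()].
#' @export
generate_epoch_series <- function(profile, days = 7, seed = 1L,
                                  nonwear_days = integer(),
                                  start_date = as.Date("2024-06-03")) {
  if (days < 1) stop_input("days must be >= 1")
  days <- as.integer(days)
  pid <- profile$participant_id[1]
  with_seed(seed, {
    awake_epochs <- 960L * 10L            # 07:00-23:00 at 6 s
    sleep_epochs <- 480L * 10L            # 23:00-07:00
    mpa_week <- max(0, profile$true_mpa_min_per_week[1]) * 10
    vpa_week <- max(0, profile$true_vpa_min_per_week[1]) * 10
    alloc <- function(total) {
      if (round(total) <= 0) return(integer(days))
      as.integer(stats::rmultinom(1, round(total), rep(1 / days, days)))
    }
    mpa_day <- alloc(mpa_week * days / 7)
    vpa_day <- alloc(vpa_week * days / 7)
    day_list <- vector("list", days)
    for (d in seq_len(days)) {
      sb_epochs <- round(pmin(pmax(
        profile$true_sb_min_per_day[1] + stats::rnorm(1, 0, 5), 0), 900) * 10)
      n_act <- mpa_day[d] + vpa_day[d]
      sb_epochs <- min(sb_epochs, awake_epochs - n_act)
      light_epochs <- awake_epochs - sb_epochs - n_act
      blocks <- c(
        chunk_blocks(sb_epochs, 400, "sb"),
        chunk_blocks(mpa_day[d], 100, "mpa"),
        chunk_blocks(vpa_day[d], 50, "vpa")
      )
      if (length(blocks)) blocks <- blocks[sample.int(length(blocks))]
      cls <- interleave_with_light(blocks, light_epochs)
      met <- numeric(awake_epochs)
      posture <- character(awake_epochs)
      i_sb <- cls == "sb"; i_li <- cls == "light"
      i_mp <- cls == "mpa"; i_vp <- cls == "vpa"
      met[i_sb] <- stats::runif(sum(i_sb), 1.10, 1.40)
      met[i_li] <- stats::runif(sum(i_li), 1.70, 2.70)
      met[i_mp] <- stats::runif(sum(i_mp), 3.30, 5.40)
      met[i_vp] <- stats::runif(sum(i_vp), 6.30, 7.50)
      posture[i_sb] <- "sitting"
      posture[i_li] <- "standing"
      posture[i_mp | i_vp] <- "active"
      day0 <- as.POSIXct(paste(start_date + (d - 1), "07:00:00"), tz = "UTC")
      awake_start <- day0 + 6 * (seq_len(awake_epochs) - 1)
      sleep_start <- day0 + 960 * 60 + 6 * (seq_len(sleep_epochs) - 1)
      day_list[[d]] <- data.frame(
        participant_id = pid,
        epoch_start = c(awake_start, sleep_start),
        met = c(met, rep(1.0, sleep_epochs)),
        posture = c(posture, rep("lying", sleep_epochs)),
        wear = !(d %in% nonwear_days),
        awake = c(rep(TRUE, awake_epochs), rep(FALSE, sleep_epochs)),
        stringsAsFactors = FALSE
      )
    }
    do.call(rbind, day_list)
  })
}

# split `total` epochs into blocks of at most `size`, labelled `label`
chunk_blocks <- function(total, size, label) {
  total <- as.integer(total)
  if (total <= 0) return(list())
  n_full <- total %/% size
  rest <- total %% size
  sizes <- c(rep(size, n_full), if (rest > 0) rest)
  lapply(sizes, function(s) list(label = label, size = s))
}

# lay out blocks separated (and flanked) by light-activity filler
interleave_with_light <- function(blocks, light_epochs) {
  k <- length(blocks)
  gaps <- k + 1L
  base <- light_epochs %/% gaps
  extra <- light_epochs %% gaps
  gap_sizes <- rep(base, gaps) + c(rep(1L, extra), rep(0L, gaps - extra))
  out <- character(0)
  for (i in seq_len(k)) {
    out <- c(out, rep("light", gap_sizes[i]),
             rep(blocks[[i]]$label, blocks[[i]]$size))
  }
  c(out, rep("light", gap_sizes[gaps]))
}

#' Generate a short raw triaxial bout
#'
#' Unit-test-scale synthesis of 100 Hz acceleration: a gravity component
#' along `orientation` plus a periodic-plus-noise dynamic component whose
#' amplitude increases rest < walk < run.
#'
#' @param activity `"rest"`, `"walk"` or `"run"`.
#' @param duration_s bout duration in seconds (>= 6).
#' @param orientation length-3 device orientation (gravity direction);
#'   normalised internally.
#' @param seed integer seed.
#' @param sampling_rate_hz sampling rate (default 100).
#' @return A [raw_triaxial()] signal.
#' @export
generate_raw_bout <- function(activity = c("rest", "walk", "run"),
                              duration_s = 60, orientation = c(0, 0, 1),
                              seed = 1L, sampling_rate_hz = 100) {
  activity <- match.arg(activity)
  if (duration_s < 6) stop_input("duration_s must be >= 6")
  g <- orientation / sqrt(sum(orientation^2))
  amp <- c(rest = 0.0015, walk = 0.12, run = 0.45)[[activity]]
  freq <- c(rest = 0.3, walk = 1.8, run = 2.8)[[activity]]
  with_seed(seed, {
    n <- round(duration_s * sampling_rate_hz)
    t <- (seq_len(n) - 1) / sampling_rate_hz
    dyn <- function() {
      amp * (sin(2 * pi * freq * t + stats::runif(1, 0, 2 * pi)) * 0.7 +
               stats::rnorm(n, 0, 0.3))
    }
    raw_triaxial(time = t,
                 x = g[1] + dyn(), y = g[2] + dyn(), z = g[3] + dyn(),
                 sampling_rate_hz = sampling_rate_hz)
  })
}
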