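#' Generate raw questionnaire responses from true behaviour
#'
#' Applies the fitness-dependent reporting model to a cohort's true
#' behaviour and emits raw response tables for all three instruments.
#' Reported weekly activity minutes are
#' `basis x group PA multiplier x mean-one lognormal noise`, reported
#' sitting is `basis x group SB multiplier x noise`, where the basis is the
#' participant's own true value, or — with probability
#' `reporting_guess_prob[group]` — a fresh draw from the group's behaviour
#' distribution (uninformed recall). Weekly totals are then decomposed into
#' days/week (uniform on 2..7) times minutes/day rounded to a 5-minute grid,
#' mimicking questionnaire response granularity, and capped at the
#' instrument plausibility ceiling.
#'
#' Domains not present in the true-behaviour profile (IPAQ walking, GPAQ
#' transport, EHIS walking/cycling) are generated from their own lognormal
#' behaviour distributions; they matter for instrument structure, not for
#' criterion validity of MVPA.
#'
#' @param profiles output of [generate_cohort()].
#' @param config the [cohort_config()] used to generate `profiles`.
#' @param seed integer seed.
#' @return List of data frames `ipaq`, `gpaq`, `ehis` (one row per
#'   participant, instrument-specific columns) plus `truth_link`, a table of
#'   the reported weekly totals before day-decomposition (used by
#'   reporting-model diagnostics).
#' @export
generate_paq_responses <- function(profiles, config = cohort_config(),
                                   seed = 1L) {
  stopifnot(inherits(config, "cohort_config"))
  n <- nrow(profiles)
  grp <- as.character(profiles$fitness_group)
  mult_pa <- config$reporting_multipliers_pa[grp]
  mult_sb <- config$reporting_multipliers_sb[grp]
  p_guess <- config$reporting_guess_prob[grp]
  cv <- config$reporting_noise_cv
  cap <- config$reported_max_min_per_week
  with_seed(seed, {
    guess <- stats::runif(n) < p_guess
    # uninformed-recall basis: redraw behaviour from the group distribution
    mvpa_mean <- config$true_mvpa_mean_by_fitness[grp]
    basis_mvpa <- profiles$true_mvpa_min_per_week
    basis_mvpa[guess] <- (mvpa_mean * rlnorm_mean1(n, config$true_mvpa_cv))[guess]
    share <- ifelse(profiles$true_mvpa_min_per_week > 0,
                    profiles$true_vpa_min_per_week /
                      profiles$true_mvpa_min_per_week, 0)
    share[guess] <- pmax(config$true_vpa_share_by_fitness[grp], 1e-6)[guess]
    basis_vpa <- basis_mvpa * share
    basis_mpa <- basis_mvpa - basis_vpa
    basis_sb <- profiles$true_sb_min_per_day
    basis_sb[guess] <- pmin(pmax(
      stats::rnorm(n, config$true_sb_mean, config$true_sb_sd), 60), 900)[guess]

    rep_mpa <- pmin(basis_mpa * mult_pa * rlnorm_mean1(n, cv), cap)
    rep_vpa <- pmin(basis_vpa * mult_pa * rlnorm_mean1(n, cv), cap)
    rep_sit <- pmin(basis_sb * mult_sb * rlnorm_mean1(n, cv), 1380)
    # auxiliary domains (walking, transport, cycling) co-vary with overall
    # activity level: people who train more also walk and cycle more
    rel <- basis_mvpa / mvpa_mean
    walk_wk <- pmin(150 * rel^0.8 * rlnorm_mean1(n, 0.4) * mult_pa *
                      rlnorm_mean1(n, cv), cap)
    transport_wk <- pmin(140 * rel^0.8 * rlnorm_mean1(n, 0.4) * mult_pa *
                           rlnorm_mean1(n, cv), cap)
    cycle_wk <- pmin(60 * rel^0.8 * rlnorm_mean1(n, 0.8) * mult_pa *
                       rlnorm_mean1(n, cv), cap)
    # GPAQ splits activity between work and leisure
    wfrac_v <- stats::runif(n, 0.2, 0.8)
    wfrac_m <- stats::runif(n, 0.2, 0.8)

    ipaq <- data.frame(
      participant_id = profiles$participant_id,
      decompose_week(rep_vpa, "vig"),
      decompose_week(rep_mpa, "mod"),
      decompose_week(walk_wk, "walk"),
      sitting_min_per_day = round(rep_sit / 5) * 5,
      stringsAsFactors = FALSE
    )
    gpaq <- data.frame(
      participant_id = profiles$participant_id,
      decompose_week(rep_vpa * wfrac_v, "work_vig"),
      decompose_week(rep_mpa * wfrac_m, "work_mod"),
      decompose_week(transport_wk, "transport"),
      decompose_week(rep_vpa * (1 - wfrac_v), "leisure_vig"),
      decompose_week(rep_mpa * (1 - wfrac_m), "leisure_mod"),
      sitting_min_per_day = round(rep_sit / 5) * 5,
      stringsAsFactors = FALSE
    )
    ehis <- data.frame(
      participant_id = profiles$participant_id,
      decompose_week(walk_wk, "walking"),
      decompose_week(cycle_wk, "cycling"),
      aerobic_days_per_week = pmin(7, ceiling(basis_mvpa / 300)),
      aerobic_min_per_week = round(pmin(basis_mvpa * mult_pa *
                                          rlnorm_mean1(n, cv), cap) / 5) * 5,
      aerobic_dialect = "week",
      sitting_category = sitting_to_category(rep_sit),
      stringsAsFactors = FALSE
    )
    truth_link <- data.frame(
      participant_id = profiles$participant_id,
      fitness_group = profiles$fitness_group,
      guess = guess,
      reported_mpa_min_wk = rep_mpa,
      reported_vpa_min_wk = rep_vpa,
      reported_mvpa_min_wk = rep_mpa + rep_vpa,
      reported_sit_min_day = rep_sit,
      stringsAsFactors = FALSE
    )
    list(ipaq = ipaq, gpaq = gpaq, ehis = ehis, truth_link = truth_link)
  })
}

# weekly minutes -> (days_per_week, min_per_day) on a 5-minute grid
decompose_week <- function(weekly, prefix) {
  n <- length(weekly)
  days <- integer(n)
  per_day <- numeric(n)
  pos <- weekly >= 2.5
  days[pos] <- sample(2:7, sum(pos), replace = TRUE)
  per_day[pos] <- pmax(5, round(weekly[pos] / days[pos] / 5) * 5)
  out <- data.frame(days, per_day)
  names(out) <- paste0(prefix, c("_days_per_week", "_min_per_day"))
  out
}

# default EHIS sitting categories (daily sitting bands)
EHIS_SITTING_LEVELS <- c("less than 4 hours", "4 to 6 hours", "6 to 8 hours",
                         "8 to 10 hours", "10 hours or more")

sitting_to_category <- function(sit_min) {
  cut(sit_min, breaks = c(-Inf, 240, 360, 480, 600, Inf),
      labels = EHIS_SITTING_LEVELS, right = FALSE)
}

#' Group-wise over-reporting ratios
#'
#' Ratio of group mean reported to group mean true minutes — the estimator
#' under which the configured reporting multipliers are recoverable (the
#' mean of individual ratios is biased upwards under uninformed recall).
#'
#' @param profiles output of [generate_cohort()].
#' @param truth_link `truth_link` element of [generate_paq_responses()].
#' @return Data frame with one row per fitness group: mean reported and true
#'   MVPA, their ratio, and the same for sitting.
#' @export
reporting_ratios <- function(profiles, truth_link) {
  m <- merge(profiles, truth_link[, c("participant_id", "reported_mvpa_min_wk",
                                      "reported_sit_min_day")],
             by = "participant_id")
  out <- do.call(rbind, lapply(FITNESS_LEVELS, function(g) {
    s <- m[m$fitness_group == g, ]
    data.frame(
      fitness_group = g, n = nrow(s),
      pa_ratio = mean(s$reported_mvpa_min_wk) / mean(s$true_mvpa_min_per_week),
      sb_ratio = mean(s$reported_sit_min_day) / mean(s$true_sb_min_per_day)
    )
  }))
  out
}

#' Write a synthetic cohort to disk
#'
#' Writes `profiles.csv`, one raw-response CSV per instrument
#' (`paq_ipaq.csv`, `paq_gpaq.csv`, `paq_ehis.csv`), optionally a long
#' `epochs.csv`, and `manifest.json` recording the configuration and seed.
#'
#' @param dir output directory (created if needed).
#' @param profiles,responses cohort pieces from [generate_cohort()] and
#'   [generate_paq_responses()].
#' @param epochs optional epoch table from [generate_epoch_series()].
#' @param config optional [cohort_config()] recorded in the manifest.
#' @return Invisibly, the vector of files written.
#' @export
write_cohort <- function(dir, profiles, responses, epochs = NULL,
                         config = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  wr <- function(df, name) {
    p <- file.path(dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    files <<- c(files, p)
  }
  wr(profiles, "profiles.csv")
  wr(responses$ipaq, "paq_ipaq.csv")
  wr(responses$gpaq, "paq_gpaq.csv")
  wr(responses$ehis, "paq_ehis.csv")
  if (!is.null(epochs)) wr(epochs, "epochs.csv")
  manifest <- list(package = "fitpaq",
                   version = as.character(utils::packageVersion("fitpaq")),
                   created = format(Sys.time(), tz = "UTC"),
                   n_participants = nrow(profiles),
                   config = if (!is.null(config)) unclass(config),
                   seed = if (!is.null(config)) config$seed,
                   files = basename(files))
  mp <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(files, mp))
}
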