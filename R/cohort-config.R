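#' Synthetic cohort configuration
#'
#' Bundles every parameter of the synthetic validation study: cohort size
#' and demographics, the latent-fitness model behind the six-minute-walk
#' distances, the true-behaviour distributions, and the fitness-dependent
#' reporting-error model that turns true behaviour into questionnaire
#' responses.
#'
#' Reported activity is true activity x a fitness-group multiplier x
#' mean-one lognormal noise; reported sitting uses the (0, 1] sedentary
#' multipliers. In addition, with probability `reporting_guess_prob[group]`
#' a participant's report is uninformed recall: the report is generated from
#' the group's behaviour distribution rather than the participant's own true
#' value. Uninformed recall leaves group-level means untouched but erodes
#' rank (criterion) validity, and making it rarer with increasing fitness is
#' what produces fitness-graded validity downstream.
#'
#' @param n_participants cohort size (>= 6).
#' @param seed integer seed making the whole cohort reproducible.
#' @param age_range length-2 numeric, years (adults; minimum 18).
#' @param age_mean,age_sd mean and SD of the (truncated) age distribution.
#' @param sex_ratio proportion of male participants in (0, 1).
#' @param fitness_latent_sd SD of the latent fitness z-score.
#' @param reporting_multipliers_pa named numeric (low/intermediate/high),
#'   multiplicative over-reporting factors (> 0) for physical activity.
#' @param reporting_multipliers_sb named numeric (low/intermediate/high),
#'   factors in (0, 1] for sedentary under-reporting.
#' @param reporting_noise_cv coefficient of variation of the mean-one
#'   lognormal reporting noise (>= 0).
#' @param reporting_guess_prob named numeric (low/intermediate/high),
#'   probability of uninformed recall per fitness group, each in [0, 1].
#' @param true_mvpa_mean_by_fitness named numeric, true mean MVPA min/week
#'   per fitness group.
#' @param true_mvpa_cv coefficient of variation of true MVPA within group.
#' @param true_vpa_share_by_fitness named numeric, expected share of MVPA
#'   performed at vigorous intensity per group (in [0, 1)).
#' @param true_sb_mean,true_sb_sd mean and SD of true awake sedentary
#'   minutes per day.
#' @param sixmwt_base six-minute-walk distance in metres at average fitness.
#' @param sixmwt_fitness_slope metres of 6MWT distance per latent-fitness SD.
#' @param sixmwt_resid_sd residual SD of 6MWT distance in metres.
#' @param reported_max_min_per_week cap on generated weekly reported minutes
#'   (instrument plausibility ceiling; default 7 x 960).
#' @return An object of class `cohort_config` (a validated list).
#' @export
cohort_config <- function(n_participants = 179,
                          seed = 1L,
                          age_range = c(18, 80),
                          age_mean = 47,
                          age_sd = 10,
                          sex_ratio = 0.42,
                          fitness_latent_sd = 1,
                          reporting_multipliers_pa = c(low = 2.5, intermediate = 1.8, high = 1.3),
                          reporting_multipliers_sb = c(low = 0.60, intermediate = 0.55, high = 0.70),
                          reporting_noise_cv = 0.25,
                          reporting_guess_prob = c(low = 0.85, intermediate = 0.45, high = 0.10),
                          true_mvpa_mean_by_fitness = c(low = 300, intermediate = 360, high = 420),
                          true_mvpa_cv = 0.5,
                          true_vpa_share_by_fitness = c(low = 0.01, intermediate = 0.02, high = 0.04),
                          true_sb_mean = 500,
                          true_sb_sd = 110,
                          sixmwt_base = 650,
                          sixmwt_fitness_slope = 80,
                          sixmwt_resid_sd = 30,
                          reported_max_min_per_week = 7 * 960) {
  check_number(n_participants, "n_participants", lower = 6)
  check_number(seed, "seed")
  if (length(age_range) != 2L || age_range[1] < 18 || diff(age_range) <= 0) {
    stop_input("age_range must be c(lo, hi) with 18 <= lo < hi")
  }
  check_number(sex_ratio, "sex_ratio", lower = 0, upper = 1)
  check_number(fitness_latent_sd, "fitness_latent_sd", lower = 0)
  check_group_map <- function(x, name, lower, upper = Inf) {
    if (!is.numeric(x) || !setequal(names(x), FITNESS_LEVELS)) {
      stop_input("`%s` must be numeric with names low/intermediate/high", name)
    }
    if (any(x <= lower - 1e-12) || any(x > upper)) {
      stop_input("`%s` values out of range", name)
    }
    x[FITNESS_LEVELS]
  }
  reporting_multipliers_pa <- check_group_map(reporting_multipliers_pa,
                                             "reporting_multipliers_pa", 0)
  reporting_multipliers_sb <- check_group_map(reporting_multipliers_sb,
                                             "reporting_multipliers_sb", 0, 1)
  reporting_guess_prob <- check_group_map(reporting_guess_prob,
                                          "reporting_guess_prob", -1e-12, 1)
  true_mvpa_mean_by_fitness <- check_group_map(true_mvpa_mean_by_fitness,
                                               "true_mvpa_mean_by_fitness", 0)
  true_vpa_share_by_fitness <- check_group_map(true_vpa_share_by_fitness,
                                               "true_vpa_share_by_fitness", -1e-12, 1)
  check_number(reporting_noise_cv, "reporting_noise_cv", lower = 0)
  check_number(true_mvpa_cv, "true_mvpa_cv", lower = 0)
  check_number(true_sb_mean, "true_sb_mean", lower = 0)
  check_number(true_sb_sd, "true_sb_sd", lower = 0)
  check_number(sixmwt_base, "sixmwt_base", lower = 1)
  check_number(sixmwt_fitness_slope, "sixmwt_fitness_slope")
  check_number(sixmwt_resid_sd, "sixmwt_resid_sd", lower = 0)
  check_number(reported_max_min_per_week, "reported_max_min_per_week", lower = 1)
  structure(list(
    n_participants = as.integer(n_participants), seed = as.integer(seed),
    age_range = age_range, age_mean = age_mean, age_sd = age_sd,
    sex_ratio = sex_ratio, fitness_latent_sd = fitness_latent_sd,
    reporting_multipliers_pa = reporting_multipliers_pa,
    reporting_multipliers_sb = reporting_multipliers_sb,
    reporting_noise_cv = reporting_noise_cv,
    reporting_guess_prob = reporting_guess_prob,
    true_mvpa_mean_by_fitness = true_mvpa_mean_by_fitness,
    true_mvpa_cv = true_mvpa_cv,
    true_vpa_share_by_fitness = true_vpa_share_by_fitness,
    true_sb_mean = true_sb_mean, true_sb_sd = true_sb_sd,
    sixmwt_base = sixmwt_base, sixmwt_fitness_slope = sixmwt_fitness_slope,
    sixmwt_resid_sd = sixmwt_resid_sd,
    reported_max_min_per_week = reported_max_min_per_week
  ), class = "cohort_config")
}

#' @export
print.cohort_config <- function(x, ...) {
  cat(sprintf("<cohort_config> n = %d, seed = %d\n", x$n_participants, x$seed))
  cat(sprintf("  PA multipliers:  %s\n",
              paste(sprintf("%s=%.2f", FITNESS_LEVELS, x$reporting_multipliers_pa),
                    collapse = ", ")))
  cat(sprintf("  SB multipliers:  %s\n",
              paste(sprintf("%s=%.2f", FITNESS_LEVELS, x$reporting_multipliers_sb),
                    collapse = ", ")))
  cat(sprintf("  guess prob:      %s\n",
              paste(sprintf("%s=%.2f", FITNESS_LEVELS, x$reporting_guess_prob),
                    collapse = ", ")))
  cat(sprintf("  noise CV = %.2f, 6MWT = %g + %g z (m)\n",
              x$reporting_noise_cv, x$sixmwt_base, x$sixmwt_fitness_slope))
  invisible(x)
}
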