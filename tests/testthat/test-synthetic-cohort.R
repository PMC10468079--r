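test_that("cohort generation is deterministic and validates its config", {
  cfg <- cohort_config(n_participants = 6, seed = 1)
  expect_identical(generate_cohort(cfg), generate_cohort(cfg))
  expect_error(cohort_config(n_participants = 3), "n_participants")
  expect_error(cohort_config(reporting_multipliers_pa = c(low = 1, high = 1)),
               "reporting_multipliers_pa")
  expect_error(cohort_config(reporting_noise_cv = -0.1),
               "reporting_noise_cv")
})

test_that("true MVPA is the sum of its moderate and vigorous parts", {
  p <- generate_cohort(cohort_config(n_participants = 50, seed = 3))
  expect_equal(p$true_mpa_min_per_week + p$true_vpa_min_per_week,
               p$true_mvpa_min_per_week)
  expect_true(all(p$true_sb_min_per_day >= 0))
  expect_true(all(p$true_mvpa_min_per_week >= 0))
  expect_equal(nrow(p), 50)
})

test_that("latent fitness drives 6MWT distance as configured", {
  # zero slope decouples fitness and walk distance
  p0 <- generate_cohort(cohort_config(n_participants = 2000, seed = 4,
                                      sixmwt_fitness_slope = 0))
  expect_lt(abs(cor(p0$latent_fitness, p0$sixmwt_m)), 0.06)

  # slope 40 m/SD: Spearman rho matches an independent re-simulation of the
  # same generative equations within Monte-Carlo error
  p40 <- generate_cohort(cohort_config(n_participants = 2000, seed = 5,
                                       sixmwt_fitness_slope = 40,
                                       sixmwt_resid_sd = 30))
  got <- cor(p40$latent_fitness, p40$sixmwt_m, method = "spearman")
  set.seed(99)
  z <- rnorm(2e5)
  d <- 650 + 40 * z + rnorm(2e5, 0, 30)
  expected <- cor(z, d, method = "spearman")
  expect_equal(got, expected, tolerance = 0.03)
})

test_that("epoch series honour the true-behaviour profile", {
  p <- generate_cohort(cohort_config(n_participants = 6, seed = 11))

  # degenerate profile: no vigorous truth -> no epoch at or above 6 MET
  p0 <- p[1, ]
  p0$true_vpa_min_per_week <- 0
  p0$true_mpa_min_per_week <- p0$true_mvpa_min_per_week
  ep0 <- generate_epoch_series(p0, days = 7, seed = 2)
  expect_true(all(ep0$met < 6.0))

  # 7 complete days: counting epochs recovers true weekly MVPA closely
  ep <- generate_epoch_series(p[2, ], days = 7, seed = 3)
  awake <- ep[ep$awake & ep$wear, ]
  mvpa_min <- sum(awake$met >= 3.0) * 6 / 60
  expect_equal(mvpa_min, p$true_mvpa_min_per_week[2], tolerance = 0.01)

  # determinism and the days >= 1 contract
  expect_identical(generate_epoch_series(p[3, ], days = 2, seed = 5),
                   generate_epoch_series(p[3, ], days = 2, seed = 5))
  expect_error(generate_epoch_series(p[3, ], days = 0, seed = 5), "days")

  # two injected non-wear days leave 5 valid days downstream
  epn <- generate_epoch_series(p[4, ], days = 7, seed = 6,
                               nonwear_days = c(2, 4))
  out <- process_epochs(epn)
  expect_equal(out$participants$n_valid_days, 5)
  expect_true(out$participants$included)
})

test_that("raw bouts order MAD by activity and set the gravity direction", {
  rest <- generate_raw_bout("rest", 30, seed = 1)
  walk <- generate_raw_bout("walk", 30, seed = 1)
  run <- generate_raw_bout("run", 30, seed = 1)
  m <- vapply(list(rest, walk, run), function(s) mean(compute_mad(s)),
              numeric(1))
  expect_true(m[1] < m[2] && m[2] < m[3])

  # orientation along the reference -> APE ~ 0; orthogonal -> ~ 90
  ref <- c(0, 0, 1)
  along <- generate_raw_bout("rest", 12, orientation = c(0, 0, 1), seed = 2)
  ortho <- generate_raw_bout("rest", 12, orientation = c(1, 0, 0), seed = 3)
  expect_lt(max(compute_ape(along, ref)), 1)
  expect_equal(mean(compute_ape(ortho, ref)), 90, tolerance = 1)
  expect_error(generate_raw_bout("swim", 30), "arg")
})

test_that("identity reporting reproduces true minutes up to day rounding", {
  cfg <- cohort_config(n_participants = 40, seed = 21,
                       reporting_multipliers_pa = c(low = 1, intermediate = 1,
                                                    high = 1),
                       reporting_multipliers_sb = c(low = 1, intermediate = 1,
                                                    high = 1),
                       reporting_noise_cv = 0,
                       reporting_guess_prob = c(low = 0, intermediate = 0,
                                                high = 0))
  p <- generate_cohort(cfg)
  r <- generate_paq_responses(p, cfg, seed = 22)
  sc <- score_ipaq_sf(r$ipaq, cleaning_rules(daily_truncate_min = Inf,
                                             max_total_daily_min = Inf))
  # day x 5-min-grid decomposition perturbs weekly totals by < days x 2.5 min
  expect_lt(max(abs(sc$mvpa_min_wk - p$true_mvpa_min_per_week)), 2 * 17.5)
  expect_equal(r$truth_link$reported_mvpa_min_wk, p$true_mvpa_min_per_week)
  expect_equal(r$truth_link$reported_sit_min_day, p$true_sb_min_per_day)
})

test_that("a fixed multiplier with zero noise scales reports exactly", {
  cfg <- cohort_config(n_participants = 30, seed = 31,
                       reporting_multipliers_pa = c(low = 2.5,
                                                    intermediate = 2.5,
                                                    high = 2.5),
                       reporting_noise_cv = 0,
                       reporting_guess_prob = c(low = 0, intermediate = 0,
                                                high = 0))
  p <- generate_cohort(cfg)
  r <- generate_paq_responses(p, cfg, seed = 32)
  expect_equal(r$truth_link$reported_mvpa_min_wk / p$true_mvpa_min_per_week,
               rep(2.5, 30))
})

test_that("group mean over-reporting ratios recover the multipliers", {
  cfg <- cohort_config(n_participants = 2000, seed = 41)
  p <- generate_cohort(cfg)
  r <- generate_paq_responses(p, cfg, seed = 42)
  rr <- reporting_ratios(p, r$truth_link)
  expect_equal(rr$pa_ratio, unname(cfg$reporting_multipliers_pa),
               tolerance = 0.05)
  expect_equal(rr$sb_ratio, unname(cfg$reporting_multipliers_sb),
               tolerance = 0.05)
})

test_that("responses are deterministic for a fixed seed and well-formed", {
  cfg <- cohort_config(n_participants = 20, seed = 51)
  p <- generate_cohort(cfg)
  r1 <- generate_paq_responses(p, cfg, seed = 52)
  r2 <- generate_paq_responses(p, cfg, seed = 52)
  expect_identical(r1, r2)
  expect_true(all(r1$ipaq$vig_days_per_week %in% 0:7))
  expect_true(all(r1$ipaq$mod_min_per_day %% 5 == 0))
  expect_true(all(as.character(r1$ehis$sitting_category) %in%
                    names(sitting_codebook())))
})
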