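test_that("Spearman validity handles monotone, antitone and tied data", {
  x <- 1:5
  g <- rep("low", 5)
  up <- spearman_validity(2 * x, x, g)
  expect_equal(up$rho[up$group == "total"], 1.0)
  down <- spearman_validity(rev(x), x, g)
  expect_equal(down$rho[down$group == "total"], -1.0)

  # ties: matches the rank-then-Pearson oracle
  set.seed(3)
  for (k in 1:10) {
    a <- sample(1:4, 5, replace = TRUE)
    b <- sample(1:4, 5, replace = TRUE)
    if (sd(a) == 0 || sd(b) == 0) next
    got <- spearman_validity(a, b, rep("low", 5))
    expect_equal(got$rho[got$group == "total"], oracle_spearman(a, b),
                 tolerance = 1e-12)
  }

  # invariant under strictly monotone transforms of either input
  set.seed(4)
  p <- rlnorm(40); q <- p * rlnorm(40, 0, 0.5)
  r0 <- spearman_validity(p, q, rep("low", 40))
  r1 <- spearman_validity(log(p), q^3, rep("low", 40))
  expect_equal(r0$rho, r1$rho)

  # fewer than 3 complete pairs is withheld, not an error
  w <- spearman_validity(c(1, 2, NA), c(1, NA, 3), rep("low", 3))
  expect_true(all(is.na(w$rho)))
  expect_equal(unique(w$withheld_reason), "too_few_pairs")
})

test_that("validity categories follow the published bands on |rho|", {
  expect_equal(categorize_validity(c(0.29, 0.30, 0.49, 0.50, 0.69, 0.70,
                                     0.89, 0.90, 0.95)),
               c("very low", "low", "low", "moderate", "moderate", "high",
                 "high", "very high", "very high"))
  expect_equal(categorize_validity(-0.55), "moderate")
  expect_error(categorize_validity(1.2), "-1, 1")
})

test_that("Bland-Altman bias and limits of agreement are exact", {
  same <- bland_altman(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$bias, 0)
  expect_equal(c(same$loa_low, same$loa_high), c(0, 0))

  # differences {-1, +1}: bias 0, sd sqrt(2), LoA +/- 2.7719
  ba <- bland_altman(c(0, 2), c(1, 1))
  expect_equal(ba$bias, 0)
  expect_equal(ba$sd_diff, sqrt(2))
  expect_equal(ba$loa_high, 1.96 * sqrt(2))
  expect_equal(ba$loa_low, -1.96 * sqrt(2))

  # antisymmetry under swapping the methods
  set.seed(6)
  a <- rnorm(30, 100, 10); b <- rnorm(30, 90, 10)
  f <- bland_altman(a, b); r <- bland_altman(b, a)
  expect_equal(f$bias, -r$bias)
  expect_equal(f$loa_low, -r$loa_high)
  expect_error(bland_altman(1, 2), "pairs")
})

test_that("about 95% of normal differences fall inside the LoA", {
  set.seed(7)
  a <- rnorm(5000); b <- rnorm(5000)
  ba <- bland_altman(a, b)
  inside <- mean(ba$pairs$diff >= ba$loa_low & ba$pairs$diff <= ba$loa_high)
  expect_equal(inside, 0.95, tolerance = 0.01)
})

test_that("equivalence bounds are the stated percentage of the reference", {
  expect_equal(equivalence_bounds(523.3, 15), 78.495, tolerance = 1e-6)
  expect_equal(round(equivalence_bounds(523.3, 15), 1), 78.5)
  expect_equal(round(equivalence_bounds(386.7, 15), 1), 58.0)
  expect_equal(equivalence_bounds(100, 0), 0)
  expect_error(equivalence_bounds(-5), "reference")
})

test_that("paired TOST matches the hand-computed confidence interval", {
  # n = 30, mean diff 20, sd 30: 90% CI = 20 +/- 1.699 x 30/sqrt(30)
  set.seed(10)
  d <- rnorm(30)
  d <- (d - mean(d)) / sd(d) * 30 + 20
  accel <- rnorm(30, 300, 50)
  ts <- tost_equivalence(accel + d, accel, bound = 58)
  expect_equal(ts$mean_diff, 20)
  expect_equal(ts$ci_low, 20 - qt(0.95, 29) * 30 / sqrt(30), tolerance = 1e-9)
  expect_equal(ts$ci_high, 20 + qt(0.95, 29) * 30 / sqrt(30), tolerance = 1e-9)
  expect_true(ts$equivalent)
  expect_equal(ts$t_lower, (20 + 58) / (30 / sqrt(30)), tolerance = 1e-9)
  expect_equal(ts$t_upper, (20 - 58) / (30 / sqrt(30)), tolerance = 1e-9)
  expect_equal(ts$df, 29)
  expect_equal(ts$t_paired, 20 / (30 / sqrt(30)), tolerance = 1e-9)

  # zero differences are trivially equivalent for any positive bound
  z <- tost_equivalence(rep(5, 10), rep(5, 10), bound = 10)
  expect_true(z$equivalent)
  expect_true(z$degenerate)

  # a mean difference outside the bound can never be equivalent
  big <- tost_equivalence(rnorm(20, 400), rnorm(20, 300), bound = 58)
  expect_false(big$equivalent)
})

test_that("TOST verdicts agree between the CI and two-one-sided-p forms", {
  set.seed(11)
  for (k in 1:50) {
    n <- sample(5:40, 1)
    d <- rnorm(n, mean = runif(1, -80, 80), sd = runif(1, 5, 120))
    b <- runif(1, 10, 100)
    ts <- tost_equivalence(d, rep(0, n), bound = b)
    ci_inside <- ts$ci_low > -b && ts$ci_high < b
    both_p <- ts$p_lower < 0.05 && ts$p_upper < 0.05
    expect_equal(ts$equivalent, ci_inside)
    expect_equal(ts$equivalent, both_p)
    # sign symmetry with symmetric bounds
    tsn <- tost_equivalence(-d, rep(0, n), bound = b)
    expect_equal(tsn$equivalent, ts$equivalent)
    expect_equal(tsn$mean_diff, -ts$mean_diff)
  }
})

test_that("group difference tests gate on normality and match the H oracle", {
  # three identical groups: H = 0, p = 1
  v <- rep(c(1, 2, 3, 4), 3)
  g <- rep(c("a", "b", "c"), each = 4)
  r <- group_difference_tests(v, g)
  expect_equal(r$statistic, 0, tolerance = 1e-12)
  expect_equal(r$p_value, 1)

  # a strongly shifted group is detected
  set.seed(12)
  v2 <- c(rnorm(20), rnorm(20), rnorm(20, 50))
  g2 <- rep(c("a", "b", "c"), each = 20)
  r2 <- group_difference_tests(v2, g2)
  expect_lt(r2$p_value, 0.05)
  shifted <- r2$pairwise[r2$pairwise$group2 == "c" |
                           r2$pairwise$group1 == "c", ]
  expect_true(all(shifted$p_adjusted < 0.05))

  # Kruskal-Wallis H equals the explicit rank-sum formula with ties
  v3 <- c(3, 1, 4, 1, 5, 9, 2, 6, 5, 3, 5)
  g3 <- c("a", "a", "a", "b", "b", "b", "b", "c", "c", "c", "c")
  r3 <- group_difference_tests(v3, g3)
  expect_equal(r3$test, "kruskal_wallis")
  expect_equal(r3$statistic, oracle_kw_h(v3, g3), tolerance = 1e-12)

  # clearly normal data with equal spread goes through ANOVA
  set.seed(13)
  v4 <- c(rnorm(40, 0), rnorm(40, 0.2), rnorm(40, 0.4))
  g4 <- rep(c("a", "b", "c"), each = 40)
  r4 <- group_difference_tests(v4, g4)
  expect_true(r4$test %in% c("anova", "kruskal_wallis"))
  if (r4$test == "anova") {
    expect_equal(r4$statistic,
                 unname(summary(aov(v4 ~ factor(g4)))[[1]]$`F value`[1]),
                 tolerance = 1e-9)
  }
  expect_error(group_difference_tests(1:3, c("a", "a", "a")), "groups")
})
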