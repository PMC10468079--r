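#' Spearman criterion validity, per fitness group and overall
#'
#' Rank correlation between a questionnaire measure and the accelerometer
#' reference, with average ranks for ties and a two-sided p-value, computed
#' within each fitness group and for the pooled total. Pairs with a missing
#' value in either arm are deleted pairwise; groups with fewer than
#' `min_pairs` complete pairs are withheld.
#'
#' @param paq,accel paired numeric vectors (questionnaire and reference).
#' @param groups factor/character of fitness-group labels, same length.
#' @param min_pairs minimum complete pairs per reported group (default 3).
#' @return Data frame: `group`, `n`, `rho`, `p_value`, `category`,
#'   `withheld_reason`.
#' @export
spearman_validity <- function(paq, accel, groups, min_pairs = 3) {
  stopifnot(length(paq) == length(accel), length(groups) == length(paq))
  one <- function(g, idx) {
    ok <- idx[!is.na(paq[idx]) & !is.na(accel[idx])]
    n <- length(ok)
    if (n < min_pairs) {
      return(data.frame(group = g, n = n, rho = NA_real_,
                        p_value = NA_real_, category = NA_character_,
                        withheld_reason = "too_few_pairs",
                        stringsAsFactors = FALSE))
    }
    ct <- suppressWarnings(stats::cor.test(paq[ok], accel[ok],
                                           method = "spearman",
                                           exact = FALSE))
    rho <- unname(ct$estimate)
    data.frame(group = g, n = n, rho = rho, p_value = ct$p.value,
               category = categorize_validity(rho),
               withheld_reason = NA_character_, stringsAsFactors = FALSE)
  }
  gl <- intersect(c(FITNESS_LEVELS, setdiff(unique(as.character(groups)),
                                            FITNESS_LEVELS)),
                  unique(as.character(groups)))
  res <- lapply(gl, function(g) one(g, which(as.character(groups) == g)))
  res[[length(res) + 1L]] <- one("total", seq_along(paq))
  do.call(rbind, res)
}

#' Categorise a validity coefficient
#'
#' Bands on the absolute coefficient: <= 0.29 very low, 0.30-0.49 low,
#' 0.50-0.69 moderate, 0.70-0.89 high, 0.90 and above very high.
#'
#' @param rho numeric vector of correlation coefficients in [-1, 1].
#' @return Character vector of band labels.
#' @export
categorize_validity <- function(rho) {
  if (any(abs(rho) > 1 + 1e-12, na.rm = TRUE)) {
    stop_input("rho must lie in [-1, 1]")
  }
  a <- abs(rho)
  out <- rep(NA_character_, length(rho))
  out[a < 0.30] <- "very low"
  out[a >= 0.30 & a < 0.50] <- "low"
  out[a >= 0.50 & a < 0.70] <- "moderate"
  out[a >= 0.70 & a < 0.90] <- "high"
  out[a >= 0.90] <- "very high"
  out
}

#' Bland-Altman agreement
#'
#' Differences are questionnaire minus accelerometer; bias is their mean and
#' the 95% limits of agreement are bias +/- 1.96 x sample SD (n - 1
#' denominator). Per-pair (mean, difference) rows are returned for plotting.
#'
#' @param paq,accel paired numeric vectors; pairs with missing values are
#'   dropped (>= 2 complete pairs required).
#' @return List of class `bland_altman`: `bias`, `sd_diff`, `loa_low`,
#'   `loa_high`, `n`, and `pairs` (data frame with `mean` and `diff`).
#' @export
bland_altman <- function(paq, accel) {
  ok <- !is.na(paq) & !is.na(accel)
  paq <- paq[ok]; accel <- accel[ok]
  if (length(paq) < 2L) stop_input("need >= 2 complete pairs")
  d <- paq - accel
  bias <- mean(d)
  sd_d <- stats::sd(d)
  structure(list(bias = bias, sd_diff = sd_d,
                 loa_low = bias - 1.96 * sd_d,
                 loa_high = bias + 1.96 * sd_d,
                 n = length(d),
                 pairs = data.frame(mean = (paq + accel) / 2, diff = d)),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman (n = %d): bias %.2f, LoA [%.2f, %.2f]\n",
              x$n, x$bias, x$loa_low, x$loa_high))
  invisible(x)
}

#' Equivalence bounds as a percentage of a reference value
#'
#' With the accelerometer as the known reference, bounds are +/- `pct`% of
#' its (pooled mean) value, expressed in raw measure units — e.g. a
#' reference of 523.3 min/day of sedentary behaviour gives +/- 78.5 min/day
#' at 15%.
#'
#' @param reference non-negative reference value in measure units.
#' @param pct percentage (default 15).
#' @return Single non-negative bound (use as +/- bound).
#' @export
equivalence_bounds <- function(reference, pct = 15) {
  check_number(reference, "reference", lower = 0)
  check_number(pct, "pct", lower = 0)
  pct / 100 * reference
}

#' Paired TOST equivalence by the confidence-interval method
#'
#' Two one-sided paired t-tests of the mean difference d = paq - accel
#' against symmetric bounds: t_lower = (mean(d) + bound) / SE and t_upper =
#' (mean(d) - bound) / SE with df = n - 1. Equivalence is declared when both
#' one-sided p-values fall below `alpha`, which is identical to the
#' (1 - 2 alpha) confidence interval of the mean difference lying inside
#' [-bound, +bound]. The ordinary paired t-test of zero difference is
#' returned alongside.
#'
#' @param paq,accel paired numeric vectors; missing pairs deleted (>= 3
#'   complete pairs required).
#' @param bound positive equivalence bound in measure units (see
#'   [equivalence_bounds()]).
#' @param alpha one-sided level (default 0.05, hence a 90% CI).
#' @return List of class `tost_result`: `mean_diff`, `se`, `df`, `ci_low`,
#'   `ci_high`, `bound`, `t_lower`, `t_upper`, `p_lower`, `p_upper`,
#'   `p_tost`, `equivalent`, `t_paired`, `p_paired`, `n`, `degenerate`.
#' @export
tost_equivalence <- function(paq, accel, bound, alpha = 0.05) {
  check_number(bound, "bound", lower = 1e-12)
  check_number(alpha, "alpha", lower = 1e-6, upper = 0.5)
  ok <- !is.na(paq) & !is.na(accel)
  d <- paq[ok] - accel[ok]
  n <- length(d)
  if (n < 3L) stop_input("need >= 3 complete pairs")
  m <- mean(d)
  s <- stats::sd(d)
  df <- n - 1
  if (s == 0) {
    eq <- abs(m) < bound
    return(structure(list(
      mean_diff = m, se = 0, df = df, ci_low = m, ci_high = m, bound = bound,
      t_lower = if (m > -bound) Inf else -Inf,
      t_upper = if (m < bound) -Inf else Inf,
      p_lower = as.numeric(!(m > -bound)), p_upper = as.numeric(!(m < bound)),
      p_tost = as.numeric(!eq), equivalent = eq,
      t_paired = if (m == 0) 0 else sign(m) * Inf,
      p_paired = as.numeric(m == 0), n = n, degenerate = TRUE),
      class = "tost_result"))
  }
  se <- s / sqrt(n)
  t_lower <- (m + bound) / se
  t_upper <- (m - bound) / se
  p_lower <- stats::pt(t_lower, df, lower.tail = FALSE)
  p_upper <- stats::pt(t_upper, df, lower.tail = TRUE)
  crit <- stats::qt(1 - alpha, df)
  structure(list(
    mean_diff = m, se = se, df = df,
    ci_low = m - crit * se, ci_high = m + crit * se, bound = bound,
    t_lower = t_lower, t_upper = t_upper,
    p_lower = p_lower, p_upper = p_upper,
    p_tost = max(p_lower, p_upper),
    equivalent = p_lower < alpha && p_upper < alpha,
    t_paired = m / se,
    p_paired = 2 * stats::pt(-abs(m / se), df),
    n = n, degenerate = FALSE), class = "tost_result")
}

#' @export
print.tost_result <- function(x, ...) {
  cat(sprintf(
    "Paired TOST: mean diff %.2f, 90%% CI [%.2f, %.2f], bounds +/- %.2f\n",
    x$mean_diff, x$ci_low, x$ci_high, x$bound))
  cat(sprintf("  t_lower = %.3f, t_upper = %.3f, p_tost = %.4g -> %s\n",
              x$t_lower, x$t_upper, x$p_tost,
              if (x$equivalent) "equivalent" else "not equivalent"))
  cat(sprintf("  paired t(%d) = %.3f, p = %.4g\n", x$df, x$t_paired,
              x$p_paired))
  invisible(x)
}

#' Between-group difference tests with normality gating
#'
#' Normality is checked per group (Lilliefors-corrected Kolmogorov-Smirnov
#' by default, since location and scale are estimated from the data; the
#' uncorrected KS variant is available). If any group departs from
#' normality at `norm_alpha` the omnibus test is Kruskal-Wallis, otherwise
#' one-way ANOVA; pairwise post-hoc comparisons use the matching test with
#' Bonferroni adjustment over the number of pairs.
#'
#' @param values numeric vector.
#' @param groups factor/character group labels (>= 2 groups with >= 2
#'   members each).
#' @param norm_alpha normality-screen level (default 0.05).
#' @param lilliefors use the estimated-parameter KS correction
#'   (default TRUE).
#' @return List of class `group_comparison`: `test`, `statistic`, `df`,
#'   `p_value`, `normality` (per-group p-values), `pairwise` (data frame
#'   with Bonferroni-adjusted p-values).
#' @export
group_difference_tests <- function(values, groups, norm_alpha = 0.05,
                                   lilliefors = TRUE) {
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]
  groups <- factor(groups[ok])
  sizes <- table(groups)
  if (length(sizes) < 2L || any(sizes < 2L)) {
    stop_input("need >= 2 groups with >= 2 members each")
  }
  norm_p <- vapply(levels(groups), function(g) {
    x <- values[groups == g]
    if (length(unique(x)) < 2L || length(x) < 5L) return(NA_real_)
    if (lilliefors) nortest::lillie.test(x)$p.value
    else suppressWarnings(stats::ks.test(x, "pnorm", mean(x),
                                         stats::sd(x)))$p.value
  }, numeric(1))
  nonnormal <- any(norm_p < norm_alpha, na.rm = TRUE) || all(is.na(norm_p))
  if (nonnormal) {
    kw <- stats::kruskal.test(values, groups)
    test <- "kruskal_wallis"
    statistic <- unname(kw$statistic)
    df <- unname(kw$parameter)
    p <- kw$p.value
    pw <- suppressWarnings(
      stats::pairwise.wilcox.test(values, groups,
                                  p.adjust.method = "bonferroni"))
  } else {
    fit <- stats::oneway.test(values ~ groups, var.equal = TRUE)
    test <- "anova"
    statistic <- unname(fit$statistic)
    df <- unname(fit$parameter[1])
    p <- fit$p.value
    pw <- stats::pairwise.t.test(values, groups,
                                 p.adjust.method = "bonferroni")
  }
  pm <- pw$p.value
  pairs <- do.call(rbind, lapply(rownames(pm), function(r) {
    cols <- colnames(pm)[!is.na(pm[r, ])]
    if (!length(cols)) return(NULL)
    data.frame(group1 = cols, group2 = r, p_adjusted = pm[r, cols],
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  structure(list(test = test, statistic = statistic, df = df, p_value = p,
                 normality = norm_p, pairwise = pairs),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s: statistic = %.3f, df = %s, p = %.4g\n", x$test,
              x$statistic, paste(signif(x$df, 4), collapse = ","), x$p_value))
  if (!is.null(x$pairwise)) {
    cat("pairwise (Bonferroni):\n")
    print(x$pairwise, row.names = FALSE)
  }
  invisible(x)
}
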