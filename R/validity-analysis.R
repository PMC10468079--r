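#' Criterion-validity and equivalence analysis of PAQs against accelerometry
#'
#' The analysis core of the package: given a per-participant study table
#' holding accelerometer reference summaries, scored questionnaire
#' summaries and a fitness-group label, computes per instrument x measure
#' (a) Spearman criterion validity with category labels, per fitness group
#' and overall, (b) Bland-Altman agreement, and (c) paired TOST equivalence
#' by the confidence-interval method with bounds of +/- `bound_pct`% of the
#' pooled accelerometer mean (sedentary behaviour in min/day, MVPA in
#' min/week), plus between-group difference tests of every analysed
#' variable.
#'
#' @param data study table with columns `participant_id`, a group column
#'   (default `tercile` with levels low/intermediate/high), accelerometer
#'   columns `accel_sb_min_day`, `accel_mpa_min_wk`, `accel_vpa_min_wk`,
#'   `accel_mvpa_min_wk`, and per instrument `<instrument>_<measure>`
#'   columns as produced by [harmonise_paq()] (e.g. `ipaq_sf_mvpa_min_wk`).
#' @param instruments character vector of instrument prefixes (default the
#'   three PAQs).
#' @param measures measures to analyse among `"sb"`, `"mpa"`, `"vpa"`,
#'   `"mvpa"`; equivalence and agreement are computed for sedentary
#'   behaviour and MVPA.
#' @param group_col name of the fitness-group column.
#' @param bound_pct equivalence bounds as a percentage of the pooled
#'   accelerometer mean (default 15).
#' @param bounds optional named numeric overriding the derived raw bounds,
#'   e.g. `c(sb = 78.5, mvpa = 58)`.
#' @param alpha one-sided TOST level (default 0.05; 90% CI).
#' @param direction `"paq_minus_accel"` (default) or `"accel_minus_paq"`;
#'   fixes the sign convention of every difference.
#' @return An object of class `paq_validity` with elements `validity`,
#'   `agreement`, `equivalence`, `group_tests`, `bounds`, `n`, `alpha`,
#'   `direction`, `call`. Methods: [print.paq_validity()],
#'   [summary.paq_validity()], [coef.paq_validity()],
#'   [plot.paq_validity()].
#' @export
validity_analysis <- function(data,
                              instruments = c("ipaq_sf", "gpaq", "ehis_paq"),
                              measures = c("sb", "mpa", "vpa", "mvpa"),
                              group_col = "tercile",
                              bound_pct = 15, bounds = NULL, alpha = 0.05,
                              direction = c("paq_minus_accel",
                                            "accel_minus_paq")) {
  direction <- match.arg(direction)
  measures <- match.arg(measures, several.ok = TRUE)
  if (!group_col %in% names(data)) {
    stop_input("group column `%s` not found", group_col)
  }
  groups <- as.character(data[[group_col]])
  suffix <- function(m) if (m == "sb") "sb_min_day" else paste0(m, "_min_wk")
  acol <- function(m) paste0("accel_", suffix(m))
  pcol <- function(ins, m) paste0(ins, "_", suffix(m))
  for (m in measures) {
    if (!acol(m) %in% names(data)) {
      stop_input("accelerometer column `%s` not found", acol(m))
    }
  }
  sgn <- if (direction == "paq_minus_accel") 1 else -1

  # derived equivalence bounds from pooled accelerometer means
  eq_measures <- intersect(measures, c("sb", "mvpa"))
  bound_tab <- do.call(rbind, lapply(eq_measures, function(m) {
    ref <- mean(data[[acol(m)]], na.rm = TRUE)
    b <- if (!is.null(bounds) && m %in% names(bounds)) bounds[[m]]
         else equivalence_bounds(ref, bound_pct)
    data.frame(measure = m, reference = ref, bound = b,
               units = if (m == "sb") "min/day" else "min/week",
               stringsAsFactors = FALSE)
  }))

  validity <- list(); agreement <- list(); equivalence <- list()
  for (ins in instruments) {
    for (m in measures) {
      pc <- pcol(ins, m)
      if (!pc %in% names(data)) next
      paq <- data[[pc]]
      if (all(is.na(paq))) next      # instrument does not resolve measure
      accel <- data[[acol(m)]]
      v <- spearman_validity(paq, accel, groups)
      v <- cbind(instrument = ins, measure = m, v)
      validity[[length(validity) + 1L]] <- v
      if (m %in% eq_measures) {
        b <- bound_tab$bound[bound_tab$measure == m]
        for (g in c(FITNESS_LEVELS, "total")) {
          idx <- if (g == "total") seq_len(nrow(data)) else which(groups == g)
          ok <- idx[!is.na(paq[idx]) & !is.na(accel[idx])]
          if (length(ok) >= 3L) {
            ba <- bland_altman(sgn * paq[ok], sgn * accel[ok])
            agreement[[length(agreement) + 1L]] <- data.frame(
              instrument = ins, measure = m, group = g, n = ba$n,
              bias = ba$bias, sd_diff = ba$sd_diff,
              loa_low = ba$loa_low, loa_high = ba$loa_high,
              stringsAsFactors = FALSE)
            ts <- tost_equivalence(sgn * paq[ok], sgn * accel[ok],
                                   bound = b, alpha = alpha)
            equivalence[[length(equivalence) + 1L]] <- data.frame(
              instrument = ins, measure = m, group = g, n = ts$n,
              mean_diff = ts$mean_diff, ci90_low = ts$ci_low,
              ci90_high = ts$ci_high, bound = b,
              t_lower = ts$t_lower, t_upper = ts$t_upper, df = ts$df,
              p_tost = ts$p_tost, equivalent = ts$equivalent,
              t_paired = ts$t_paired, p_paired = ts$p_paired,
              stringsAsFactors = FALSE)
          }
        }
      }
    }
  }

  group_tests <- list()
  in_groups <- groups %in% FITNESS_LEVELS
  for (m in measures) {
    x <- data[[acol(m)]]
    ok <- in_groups & !is.na(x)
    if (sum(ok) >= 6 && length(unique(groups[ok])) >= 2) {
      group_tests[[acol(m)]] <- group_difference_tests(x[ok], groups[ok])
    }
  }

  structure(list(
    validity = do.call(rbind, validity),
    agreement = do.call(rbind, agreement),
    equivalence = do.call(rbind, equivalence),
    group_tests = group_tests,
    bounds = bound_tab,
    n = nrow(data),
    alpha = alpha,
    direction = direction,
    call = match.call()
  ), class = "paq_validity")
}

#' @export
print.paq_validity <- function(x, digits = 3, ...) {
  cat("Criterion validity of physical activity questionnaires\n")
  cat(sprintf("  participants: %d; difference direction: %s\n", x$n,
              x$direction))
  if (!is.null(x$bounds)) {
    for (i in seq_len(nrow(x$bounds))) {
      cat(sprintf("  equivalence bounds (%s): +/- %.1f %s\n",
                  toupper(x$bounds$measure[i]), x$bounds$bound[i],
                  x$bounds$units[i]))
    }
  }
  cat("\nSpearman validity (rho):\n")
  print(coef(x), digits = digits)
  invisible(x)
}

#' Rho matrix of a fitted validity analysis
#'
#' @param object a `paq_validity` object.
#' @param ... unused.
#' @return Numeric matrix of Spearman coefficients, one row per
#'   instrument:measure, columns low/intermediate/high/total.
#' @export
coef.paq_validity <- function(object, ...) {
  v <- object$validity
  rows <- unique(paste(v$instrument, v$measure, sep = ":"))
  cols <- c(FITNESS_LEVELS, "total")
  m <- matrix(NA_real_, length(rows), length(cols),
              dimnames = list(rows, cols))
  for (i in seq_len(nrow(v))) {
    m[paste(v$instrument[i], v$measure[i], sep = ":"), v$group[i]] <- v$rho[i]
  }
  m
}

#' Summarise a fitted validity analysis
#'
#' @param object a `paq_validity` object.
#' @param ... unused.
#' @return Object of class `summary.paq_validity` printing the validity
#'   table with categories, the equivalence verdicts and the group tests.
#' @export
summary.paq_validity <- function(object, ...) {
  structure(list(x = object), class = "summary.paq_validity")
}

#' @export
print.summary.paq_validity <- function(x, ...) {
  obj <- x$x
  print(obj)
  cat("\nValidity categories:\n")
  print(obj$validity[, c("instrument", "measure", "group", "n", "rho",
                         "p_value", "category")], row.names = FALSE,
        digits = 3)
  if (!is.null(obj$equivalence)) {
    cat("\nPaired TOST equivalence (90% CI vs bounds):\n")
    print(obj$equivalence[, c("instrument", "measure", "group", "n",
                              "mean_diff", "ci90_low", "ci90_high", "bound",
                              "t_paired", "df", "p_paired", "equivalent")],
          row.names = FALSE, digits = 3)
  }
  for (nm in names(obj$group_tests)) {
    cat(sprintf("\nBetween-group test for %s:\n", nm))
    print(obj$group_tests[[nm]])
  }
  invisible(x)
}

#' Plot a fitted validity analysis
#'
#' `which = "equivalence"` draws the mean differences with 90% confidence
#' intervals against the equivalence bounds (dotted), per instrument and
#' group; `which = "agreement"` draws the Bland-Altman summary (bias and
#' limits of agreement) per instrument and group.
#'
#' @param x a `paq_validity` object.
#' @param which `"equivalence"` or `"agreement"`.
#' @param measure which measure to draw (default `"mvpa"`).
#' @param ... passed to [graphics::plot()].
#' @return Invisibly, `x`.
#' @export
plot.paq_validity <- function(x, which = c("equivalence", "agreement"),
                              measure = "mvpa", ...) {
  which <- match.arg(which)
  tab <- if (which == "equivalence") x$equivalence else x$agreement
  tab <- tab[tab$measure == measure, , drop = FALSE]
  if (is.null(tab) || nrow(tab) == 0L) {
    stop_input("nothing to plot for measure `%s`", measure)
  }
  lab <- paste(tab$instrument, tab$group, sep = "\n")
  if (which == "equivalence") {
    lo <- tab$ci90_low; hi <- tab$ci90_high; ctr <- tab$mean_diff
    b <- max(tab$bound)
  } else {
    lo <- tab$loa_low; hi <- tab$loa_high; ctr <- tab$bias
    b <- NA
  }
  ylim <- range(c(lo, hi, b, -b), na.rm = TRUE)
  graphics::plot(seq_along(ctr), ctr, ylim = ylim, xaxt = "n",
                 xlab = "", ylab = sprintf("difference (%s)", measure),
                 pch = 19, ...)
  graphics::axis(1, at = seq_along(ctr), labels = lab, cex.axis = 0.6,
                 las = 2)
  graphics::arrows(seq_along(ctr), lo, seq_along(ctr), hi, angle = 90,
                   code = 3, length = 0.04)
  graphics::abline(h = 0, col = "grey")
  if (which == "equivalence") {
    graphics::abline(h = c(-b, b), lty = 3)
  }
  invisible(x)
}
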