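#' Assign an adult age band
#'
#' Bands 18-34.99, 35-49.99, 50-64.99 and 65+, left-closed and right-open at
#' 35, 50 and 65 years.
#'
#' @param age numeric vector of ages in years (>= 18).
#' @return Factor with the four band labels.
#' @export
assign_age_band <- function(age) {
  if (any(is.na(age)) || any(age < 18)) {
    stop_input("age must be >= 18 and non-missing")
  }
  cut(age, breaks = c(18, 35, 50, 65, Inf), right = FALSE,
      labels = c("18-34.99", "35-49.99", "50-64.99", "65+"),
      include.lowest = TRUE)
}

#' Assign fitness terciles from six-minute-walk distance
#'
#' Within each sex x age-band cell, participants are ordered by ascending
#' 6MWT distance (ties broken by participant id) and split at ranks
#' ceiling(n/3) and ceiling(2n/3) into low / intermediate / high fitness, so
#' cell group sizes differ by at most one. Cells with fewer than
#' `min_cell_size` members fall back, with a warning, to tercile cuts pooled
#' over all age bands of the same sex. Participants with a missing 6MWT are
#' excluded with a reason code.
#'
#' @param profiles data frame with `participant_id`, `sex`, `age`,
#'   `sixmwt_m`.
#' @param min_cell_size smallest cell split on its own (default 3).
#' @return Data frame: `participant_id`, `sex`, `age_band`, `sixmwt_m`,
#'   `tercile` (factor low/intermediate/high, `NA` if excluded),
#'   `exclusion_reason`.
#' @export
assign_terciles <- function(profiles, min_cell_size = 3) {
  out <- data.frame(
    participant_id = profiles$participant_id,
    sex = profiles$sex,
    age_band = assign_age_band(profiles$age),
    sixmwt_m = profiles$sixmwt_m,
    tercile = factor(NA_character_, levels = FITNESS_LEVELS),
    exclusion_reason = NA_character_,
    stringsAsFactors = FALSE
  )
  missing_6mwt <- is.na(out$sixmwt_m)
  out$exclusion_reason[missing_6mwt] <- "missing_6mwt"
  ok <- which(!missing_6mwt)
  cell <- interaction(out$sex, out$age_band, drop = TRUE)
  for (cl in levels(cell)) {
    idx <- ok[cell[ok] == cl]
    if (length(idx) == 0L) next
    if (length(idx) < min_cell_size) {
      warning(sprintf(
        "cell %s has %d member(s) (< %d); using sex-pooled tercile cuts",
        cl, length(idx), min_cell_size))
      sex_i <- out$sex[idx[1]]
      pool <- ok[out$sex[ok] == sex_i]
      pooled <- rank_terciles(out$sixmwt_m[pool], out$participant_id[pool])
      out$tercile[idx] <- pooled[match(idx, pool)]
    } else {
      out$tercile[idx] <- rank_terciles(out$sixmwt_m[idx],
                                        out$participant_id[idx])
    }
  }
  out
}

#' Median/IQR descriptives by fitness group and sex
#'
#' Table-1-style descriptives: the median and interquartile range (Q3 - Q1,
#' linear-interpolation a.k.a. type-7 quantiles) of each requested variable,
#' within fitness group by sex and for each group total.
#'
#' @param data data frame containing `tercile`, `sex` and the variables.
#' @param variables character vector of numeric column names to summarise.
#' @return Long data frame: `tercile`, `sex` (male/female/total),
#'   `variable`, `n`, `median`, `iqr` (missing values dropped per cell;
#'   empty cells reported as `NA`).
#' @export
group_descriptives <- function(data, variables) {
  miss <- setdiff(variables, names(data))
  if (length(miss)) stop_input("variables not found: %s",
                               paste(miss, collapse = ", "))
  rows <- list()
  for (g in FITNESS_LEVELS) {
    for (s in c("male", "female", "total")) {
      sub <- data[!is.na(data$tercile) & data$tercile == g &
                    (s == "total" | data$sex == s), , drop = FALSE]
      for (v in variables) {
        x <- sub[[v]][!is.na(sub[[v]])]
        rows[[length(rows) + 1L]] <- data.frame(
          tercile = g, sex = s, variable = v, n = length(x),
          median = if (length(x)) stats::median(x) else NA_real_,
          iqr = if (length(x)) unname(diff(stats::quantile(x, c(0.25, 0.75),
                                                           type = 7)))
                else NA_real_,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  do.call(rbind, rows)
}
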