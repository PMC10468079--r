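#' Cleaning rules for questionnaire scoring
#'
#' Defaults follow the official IPAQ short-form data-processing rules:
#' per-domain daily minutes above 180 are truncated to 180, and a
#' participant whose summed daily activity exceeds 960 minutes is marked
#' invalid. Both are configurable; every action taken is logged in the
#' summary's `cleaning_codes`.
#'
#' @param daily_truncate_min per-domain daily truncation in minutes
#'   (default 180; `Inf` disables).
#' @param max_total_daily_min plausibility ceiling on summed daily activity
#'   minutes (default 960; `Inf` disables).
#' @param mvpa_includes_walking logical: add walking (IPAQ) / transport
#'   (GPAQ) minutes into MVPA (default FALSE, so MVPA = moderate +
#'   vigorous).
#' @return An object of class `cleaning_rules`.
#' @export
cleaning_rules <- function(daily_truncate_min = 180,
                           max_total_daily_min = 960,
                           mvpa_includes_walking = FALSE) {
  check_number(daily_truncate_min, "daily_truncate_min", lower = 0)
  check_number(max_total_daily_min, "max_total_daily_min", lower = 0)
  check_flag(mvpa_includes_walking, "mvpa_includes_walking")
  structure(list(daily_truncate_min = daily_truncate_min,
                 max_total_daily_min = max_total_daily_min,
                 mvpa_includes_walking = mvpa_includes_walking),
            class = "cleaning_rules")
}

# weekly minutes for one domain, with truncation logging;
# returns list(weekly, truncated)
domain_weekly <- function(days, per_day, truncate_min) {
  days <- ifelse(is.na(days), 0, days)
  per_day <- ifelse(is.na(per_day), 0, per_day)
  truncated <- per_day > truncate_min
  list(weekly = days * pmin(per_day, truncate_min), truncated = truncated)
}

paste_codes <- function(...) {
  m <- cbind(...)
  apply(m, 1, function(r) paste(r[nzchar(r)], collapse = ";"))
}

#' Score IPAQ short form responses
#'
#' Weekly minutes per domain are days x daily minutes after cleaning;
#' moderate minutes become MPA, vigorous VPA, walking is kept separate (and
#' optionally folded into MVPA), and reported sitting is the daily sedentary
#' estimate.
#'
#' @param resp data frame with columns `participant_id`,
#'   `vig_days_per_week`, `vig_min_per_day`, `mod_days_per_week`,
#'   `mod_min_per_day`, `walk_days_per_week`, `walk_min_per_day`,
#'   `sitting_min_per_day` (NA allowed, treated as missing).
#' @param rules a [cleaning_rules()].
#' @return Data frame (one row per participant): `participant_id`,
#'   `instrument`, `mpa_min_wk`, `vpa_min_wk`, `mvpa_min_wk`,
#'   `walking_min_wk`, `sb_min_day`, `valid`, `cleaning_codes`.
#' @export
score_ipaq_sf <- function(resp, rules = cleaning_rules()) {
  vig <- domain_weekly(resp$vig_days_per_week, resp$vig_min_per_day,
                       rules$daily_truncate_min)
  mod <- domain_weekly(resp$mod_days_per_week, resp$mod_min_per_day,
                       rules$daily_truncate_min)
  walk <- domain_weekly(resp$walk_days_per_week, resp$walk_min_per_day,
                        rules$daily_truncate_min)
  total_daily <- ifelse(is.na(resp$vig_min_per_day), 0, resp$vig_min_per_day) +
    ifelse(is.na(resp$mod_min_per_day), 0, resp$mod_min_per_day) +
    ifelse(is.na(resp$walk_min_per_day), 0, resp$walk_min_per_day)
  all_missing <- is.na(resp$vig_days_per_week) & is.na(resp$mod_days_per_week) &
    is.na(resp$walk_days_per_week)
  over_total <- total_daily > rules$max_total_daily_min
  mvpa <- mod$weekly + vig$weekly +
    if (rules$mvpa_includes_walking) walk$weekly else 0
  data.frame(
    participant_id = resp$participant_id,
    instrument = "ipaq_sf",
    mpa_min_wk = mod$weekly,
    vpa_min_wk = vig$weekly,
    mvpa_min_wk = mvpa,
    walking_min_wk = walk$weekly,
    sb_min_day = resp$sitting_min_per_day,
    valid = !all_missing & !over_total,
    cleaning_codes = paste_codes(
      ifelse(vig$truncated | mod$truncated | walk$truncated,
             "daily_truncated_180", ""),
      ifelse(over_total, "total_daily_gt_960", ""),
      ifelse(all_missing, "all_pa_missing", "")),
    stringsAsFactors = FALSE
  )
}

#' Score GPAQ responses
#'
#' Vigorous minutes are summed over the work and leisure domains, moderate
#' minutes over work, leisure and transport — the GPAQ analysis-guide
#' convention of counting transport activity as moderate intensity
#' (configurable via `transport_as_mpa`).
#'
#' @param resp data frame with columns `participant_id` and, for each domain
#'   in `work_vig`, `work_mod`, `transport`, `leisure_vig`, `leisure_mod`:
#'   `<domain>_days_per_week` and `<domain>_min_per_day`; plus
#'   `sitting_min_per_day`.
#' @param rules a [cleaning_rules()].
#' @param transport_as_mpa count transport toward MPA (default TRUE).
#' @return Data frame shaped like [score_ipaq_sf()] output; `walking_min_wk`
#'   carries the transport minutes.
#' @export
score_gpaq <- function(resp, rules = cleaning_rules(),
                       transport_as_mpa = TRUE) {
  dom <- function(d) domain_weekly(resp[[paste0(d, "_days_per_week")]],
                                   resp[[paste0(d, "_min_per_day")]],
                                   rules$daily_truncate_min)
  wv <- dom("work_vig"); wm <- dom("work_mod"); tr <- dom("transport")
  lv <- dom("leisure_vig"); lm <- dom("leisure_mod")
  vpa <- wv$weekly + lv$weekly
  mpa <- wm$weekly + lm$weekly + if (transport_as_mpa) tr$weekly else 0
  per_day_cols <- paste0(c("work_vig", "work_mod", "transport",
                           "leisure_vig", "leisure_mod"), "_min_per_day")
  total_daily <- Reduce(`+`, lapply(per_day_cols, function(cn) {
    ifelse(is.na(resp[[cn]]), 0, resp[[cn]])
  }))
  day_cols <- paste0(c("work_vig", "work_mod", "transport",
                       "leisure_vig", "leisure_mod"), "_days_per_week")
  all_missing <- Reduce(`&`, lapply(day_cols, function(cn) is.na(resp[[cn]])))
  over_total <- total_daily > rules$max_total_daily_min
  truncated <- wv$truncated | wm$truncated | tr$truncated |
    lv$truncated | lm$truncated
  mvpa <- mpa + vpa
  data.frame(
    participant_id = resp$participant_id,
    instrument = "gpaq",
    mpa_min_wk = mpa,
    vpa_min_wk = vpa,
    mvpa_min_wk = mvpa,
    walking_min_wk = tr$weekly,
    sb_min_day = resp$sitting_min_per_day,
    valid = !all_missing & !over_total,
    cleaning_codes = paste_codes(
      ifelse(truncated, "daily_truncated_180", ""),
      ifelse(over_total, "total_daily_gt_960", ""),
      ifelse(all_missing, "all_pa_missing", "")),
    stringsAsFactors = FALSE
  )
}

#' Codebook mapping EHIS sitting categories to daily minutes
#'
#' Interval midpoints; the open-ended top category is scored at its lower
#' bound plus half the preceding interval's width.
#'
#' @param levels,minutes parallel category labels and minute values. The
#'   default covers the bands <4 h, 4-6 h, 6-8 h, 8-10 h, and 10 h or more
#'   (120, 300, 420, 540, 660 minutes).
#' @return Named numeric vector (class `sitting_codebook`).
#' @export
sitting_codebook <- function(levels = EHIS_SITTING_LEVELS,
                             minutes = c(120, 300, 420, 540, 660)) {
  if (length(levels) != length(minutes)) {
    stop_input("levels and minutes must have equal length")
  }
  structure(stats::setNames(minutes, levels), class = "sitting_codebook")
}

#' Score EHIS-PAQ responses
#'
#' The instrument does not measure total activity by intensity; its MVPA
#' composite is aerobic sports/fitness/recreation minutes plus walking plus
#' cycling, all weekly. Sitting is reported either in minutes or as an
#' ordered category decoded through a [sitting_codebook()].
#'
#' @param resp data frame with columns `participant_id`,
#'   `walking_days_per_week`, `walking_min_per_day`, `cycling_days_per_week`,
#'   `cycling_min_per_day`, `aerobic_days_per_week`, aerobic minutes as
#'   `aerobic_min_per_week` or `aerobic_min_per_day` (declared per row in
#'   `aerobic_dialect`, `"week"` or `"day"`), and `sitting_category` or
#'   `sitting_min_per_day`.
#' @param codebook a [sitting_codebook()]; required when sitting is
#'   categorical.
#' @param rules a [cleaning_rules()].
#' @return Data frame shaped like [score_ipaq_sf()] output; `mpa_min_wk` and
#'   `vpa_min_wk` are `NA` (the instrument does not resolve intensity).
#' @export
score_ehis <- function(resp, codebook = sitting_codebook(),
                       rules = cleaning_rules()) {
  walk <- domain_weekly(resp$walking_days_per_week, resp$walking_min_per_day,
                        rules$daily_truncate_min)
  cyc <- domain_weekly(resp$cycling_days_per_week, resp$cycling_min_per_day,
                       rules$daily_truncate_min)
  dialect <- resp$aerobic_dialect %||% rep("week", nrow(resp))
  aero <- ifelse(dialect == "day",
                 ifelse(is.na(resp$aerobic_days_per_week), 0,
                        resp$aerobic_days_per_week) *
                   ifelse(is.na(resp$aerobic_min_per_day), 0,
                          pmin(resp$aerobic_min_per_day,
                               rules$daily_truncate_min)),
                 ifelse(is.na(resp$aerobic_min_per_week), 0,
                        resp$aerobic_min_per_week))
  if ("sitting_min_per_day" %in% names(resp)) {
    sb <- resp$sitting_min_per_day
    bad_cat <- rep(FALSE, nrow(resp))
  } else {
    cat_chr <- as.character(resp$sitting_category)
    known <- cat_chr %in% names(codebook)
    sb <- ifelse(known, unclass(codebook)[cat_chr], NA_real_)
    bad_cat <- !known & !is.na(cat_chr)
  }
  data.frame(
    participant_id = resp$participant_id,
    instrument = "ehis_paq",
    mpa_min_wk = NA_real_,
    vpa_min_wk = NA_real_,
    mvpa_min_wk = aero + walk$weekly + cyc$weekly,
    walking_min_wk = walk$weekly,
    sb_min_day = sb,
    valid = !bad_cat,
    cleaning_codes = paste_codes(
      ifelse(bad_cat, "sitting_category_unknown", ""),
      ifelse(walk$truncated | cyc$truncated, "daily_truncated_180", "")),
    stringsAsFactors = FALSE
  )
}

#' Harmonise per-instrument summaries into a wide participant table
#'
#' One row per participant, columns `<instrument>_<measure>`; participants
#' missing any instrument are retained with missing cells and flagged
#' `complete = FALSE` (a validation analysis can then restrict itself to
#' participants who completed all instruments).
#'
#' @param ... scored summary data frames (outputs of the `score_*`
#'   functions), or a single list of them.
#' @return Wide data frame keyed by `participant_id` with a `complete` flag.
#' @export
harmonise_paq <- function(...) {
  parts <- list(...)
  if (length(parts) == 1L && is.list(parts[[1]]) &&
      !is.data.frame(parts[[1]])) {
    parts <- parts[[1]]
  }
  long <- do.call(rbind, parts)
  if (anyDuplicated(long[, c("participant_id", "instrument")])) {
    stop_input("duplicate instrument rows for a participant")
  }
  instruments <- unique(long$instrument)
  ids <- unique(long$participant_id)
  out <- data.frame(participant_id = ids, stringsAsFactors = FALSE)
  measures <- c("mpa_min_wk", "vpa_min_wk", "mvpa_min_wk", "walking_min_wk",
                "sb_min_day", "valid")
  for (ins in instruments) {
    sub <- long[long$instrument == ins, ]
    m <- match(ids, sub$participant_id)
    for (ms in measures) {
      out[[paste(ins, ms, sep = "_")]] <- sub[[ms]][m]
    }
  }
  out$complete <- Reduce(`&`, lapply(instruments, function(ins) {
    !is.na(out[[paste(ins, "mvpa_min_wk", sep = "_")]])
  }))
  out
}
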