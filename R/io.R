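#' Join accelerometer, questionnaire and grouping results into a study table
#'
#' Produces the canonical per-participant analysis table consumed by
#' [validity_analysis()]: accelerometer summaries get an `accel_` prefix,
#' questionnaire summaries keep their `<instrument>_<measure>` names, and
#' the fitness tercile is attached.
#'
#' @param accel per-participant accelerometer summaries (the `participants`
#'   element of [process_epochs()] or [simulate_device_summaries()]).
#' @param paq_wide harmonised questionnaire table from [harmonise_paq()].
#' @param assignments output of [assign_terciles()].
#' @param complete_only keep only participants with all instruments scored
#'   and an accelerometer summary flagged `included` (default TRUE).
#' @return One row per participant; inclusion flags consistent across
#'   sources.
#' @export
build_study_table <- function(accel, paq_wide, assignments,
                              complete_only = TRUE) {
  a <- accel
  names(a)[names(a) == "sb_min_per_day"] <- "accel_sb_min_day"
  names(a)[names(a) == "mpa_min_per_week"] <- "accel_mpa_min_wk"
  names(a)[names(a) == "vpa_min_per_week"] <- "accel_vpa_min_wk"
  names(a)[names(a) == "mvpa_min_per_week"] <- "accel_mvpa_min_wk"
  out <- merge(a, paq_wide, by = "participant_id")
  out <- merge(out,
               assignments[, c("participant_id", "sex", "age_band",
                               "sixmwt_m", "tercile")],
               by = "participant_id")
  if (complete_only) {
    keep <- out$included & out$complete & !is.na(out$tercile)
    out <- out[keep, , drop = FALSE]
  }
  out[order(out$participant_id), , drop = FALSE]
}

#' Run the full synthetic validation study
#'
#' simulate -> score -> group -> validate, end to end: generates a cohort,
#' simulates the accelerometer arm, generates and scores all three
#' questionnaires, assigns 6MWT fitness terciles, fits the validity
#' analysis, and (optionally) writes the report tables and a JSON run
#' manifest. Deterministic for a fixed configuration.
#'
#' @param config a [cohort_config()]; its seed drives every stage.
#' @param out_dir optional output directory; when given, descriptives,
#'   validity, agreement and equivalence CSVs plus `manifest.json` are
#'   written there.
#' @param rules [cleaning_rules()] for questionnaire scoring.
#' @return List: `profiles`, `accel`, `responses`, `scored` (harmonised wide
#'   table), `assignments`, `study` (analysis table), `fit` (the
#'   `paq_validity` object), `descriptives`, `files`.
#' @export
run_pipeline <- function(config = cohort_config(), out_dir = NULL,
                         rules = cleaning_rules()) {
  profiles <- generate_cohort(config)
  accel <- simulate_device_summaries(profiles,
                                     seed = child_seed(config$seed, 1))
  responses <- generate_paq_responses(profiles, config,
                                      seed = child_seed(config$seed, 2))
  scored <- harmonise_paq(
    score_ipaq_sf(responses$ipaq, rules),
    score_gpaq(responses$gpaq, rules),
    score_ehis(responses$ehis, rules = rules)
  )
  assignments <- assign_terciles(profiles)
  study <- build_study_table(accel, scored, assignments)
  fit <- validity_analysis(study)
  desc_vars <- c("sixmwt_m", "accel_sb_min_day", "accel_mpa_min_wk",
                 "accel_vpa_min_wk", "accel_mvpa_min_wk",
                 "ipaq_sf_mvpa_min_wk", "gpaq_mvpa_min_wk",
                 "ehis_paq_mvpa_min_wk")
  descriptives <- group_descriptives(study,
                                     intersect(desc_vars, names(study)))
  files <- character(0)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    wr <- function(df, name) {
      p <- file.path(out_dir, name)
      utils::write.csv(df, p, row.names = FALSE)
      files <<- c(files, p)
    }
    wr(descriptives, "descriptives.csv")
    wr(fit$validity, "validity.csv")
    wr(fit$agreement, "agreement.csv")
    wr(fit$equivalence, "equivalence.csv")
    wr(study, "study_table.csv")
    manifest <- list(package = "fitpaq",
                     version = as.character(utils::packageVersion("fitpaq")),
                     seed = config$seed,
                     n_participants = config$n_participants,
                     n_analysed = nrow(study),
                     config = unclass(config),
                     files = basename(files))
    mp <- file.path(out_dir, "manifest.json")
    jsonlite::write_json(manifest, mp, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
    files <- c(files, mp)
  }
  list(profiles = profiles, accel = accel, responses = responses,
       scored = scored, assignments = assignments, study = study,
       fit = fit, descriptives = descriptives, files = files)
}

#' Rename and decode columns of an external study table
#'
#' Applies a user-supplied mapping from dataset-specific variable names to
#' the canonical column names used by [validity_analysis()]; unmapped
#' columns are preserved untouched.
#'
#' @param data a data frame (e.g. read from an SPSS export).
#' @param mapping named character vector: `c(canonical = "dataset_name",
#'   ...)`.
#' @return The data frame with mapped columns renamed.
#' @export
map_study_columns <- function(data, mapping) {
  if (is.null(names(mapping)) || any(!nzchar(names(mapping)))) {
    stop_input("mapping must be a fully named character vector")
  }
  for (canonical in names(mapping)) {
    src <- mapping[[canonical]]
    if (!src %in% names(data)) {
      stop_input("mapped column `%s` (-> `%s`) not found in data", src,
                 canonical)
    }
    names(data)[names(data) == src] <- canonical
  }
  data
}

#' Read an SPSS .sav study dataset
#'
#' Thin wrapper over `foreign::read.spss()` that decodes labelled
#' categoricals, propagates declared missing values as `NA`, and applies an
#' optional column mapping (see [map_study_columns()]).
#'
#' @param path path to a readable .sav file.
#' @param mapping optional named character vector passed to
#'   [map_study_columns()].
#' @return A data frame.
#' @export
read_sav <- function(path, mapping = NULL) {
  if (!requireNamespace("foreign", quietly = TRUE)) {
    stop_input("package `foreign` is required to read .sav files")
  }
  if (!file.exists(path)) stop_input("file not found: %s", path)
  df <- suppressWarnings(
    foreign::read.spss(path, to.data.frame = TRUE, use.value.labels = TRUE)
  )
  if (!is.null(mapping)) df <- map_study_columns(df, mapping)
  df
}

#' Reproduce the validity and equivalence analysis from a deposited dataset
#'
#' Runs [validity_analysis()] on an external per-participant dataset (for
#' example a study's deposited SPSS file) after column mapping. Participants
#' with a missing fitness group are dropped.
#'
#' @param path path to the .sav file.
#' @param mapping named character vector mapping canonical column names
#'   (`tercile`, `accel_mvpa_min_wk`, `ipaq_sf_mvpa_min_wk`, ...) to the
#'   dataset's variable names.
#' @param ... passed to [validity_analysis()].
#' @return A `paq_validity` object.
#' @export
reproduce_s1 <- function(path, mapping, ...) {
  df <- read_sav(path, mapping)
  if (!"tercile" %in% names(df)) {
    stop_input("mapping must provide a `tercile` column")
  }
  df <- df[!is.na(df$tercile), , drop = FALSE]
  validity_analysis(df, ...)
}
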