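#' Read and write the pipeline's CSV schemas
#'
#' CSV dialect: UTF-8, comma-separated, header row required, missing values
#' as empty fields. The milestone age column additionally accepts the
#' literal `"never"`, parsed to `never_observed = TRUE`.
#'
#' @param path File path.
#' @return A tibble in the corresponding schema.
#' @name nda_io
NULL

#' @describeIn nda_io child-level cohort table (`child_id`, `site`, `sex`,
#'   `ga_weeks`, `neuro_morbidity`, `maternal_mh`,
#'   `cbcl_attention_centile`, `cbcl_emotional_centile`, `age_months`,
#'   `assessment_complete`).
#' @export
read_cohort_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, na = "")
  need <- c("child_id", "site", "sex", "ga_weeks", "neuro_morbidity",
            "maternal_mh", "cbcl_attention_centile",
            "cbcl_emotional_centile", "age_months", "assessment_complete")
  check_schema(df, need, path)
  df$child_id <- as.character(df$child_id)
  df$neuro_morbidity <- as.logical(df$neuro_morbidity)
  df$maternal_mh <- as.logical(df$maternal_mh)
  df$assessment_complete <- as.logical(df$assessment_complete)
  df
}

#' @describeIn nda_io long-format item responses (`child_id`, `item_id`,
#'   `score`).
#' @export
read_items_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, na = "",
                        col_types = readr::cols(
                          child_id = readr::col_character(),
                          item_id = readr::col_character(),
                          score = readr::col_double()))
  check_schema(df, c("child_id", "item_id", "score"), path)
  df
}

#' @describeIn nda_io vision measures (`child_id`, `acuity_logmar`,
#'   `contrast_percent`).
#' @export
read_vision_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, na = "")
  check_schema(df, c("child_id", "acuity_logmar", "contrast_percent"), path)
  df
}

#' @describeIn nda_io milestone reports (`child_id`, `milestone`,
#'   `age_months` numeric or `"never"`).
#' @export
read_milestones_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, na = "",
                        col_types = readr::cols(
                          child_id = readr::col_character(),
                          milestone = readr::col_character(),
                          age_months = readr::col_character()))
  check_schema(df, c("child_id", "milestone", "age_months"), path)
  never <- !is.na(df$age_months) & df$age_months == "never"
  age <- suppressWarnings(as.numeric(df$age_months))
  bad <- !never & !is.na(df$age_months) & is.na(age)
  if (any(bad)) {
    abort(sprintf("malformed milestone age in row %d of %s",
                  which(bad)[1], path))
  }
  df$age_months <- ifelse(never, NA_real_, age)
  df$never_observed <- never
  df
}

check_schema <- function(df, need, path) {
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) {
    abort(paste0(path, " lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  invisible(df)
}

#' Write a generated synthetic cohort to CSV files
#'
#' Writes the four pipeline input CSVs (cohort, items, vision, milestones)
#' plus a `ground_truth.json`, using the same schemas the readers parse.
#'
#' @param syn An `nda_cohort` from [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the files written, invisibly.
#' @export
write_cohort_csvs <- function(syn, dir) {
  stopifnot(inherits(syn, "nda_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    cohort = file.path(dir, "cohort.csv"),
    items = file.path(dir, "items.csv"),
    vision = file.path(dir, "vision.csv"),
    milestones = file.path(dir, "milestones.csv"),
    ground_truth = file.path(dir, "ground_truth.json")
  )
  readr::write_csv(syn$cohort, paths[["cohort"]], na = "")
  readr::write_csv(syn$responses, paths[["items"]], na = "")
  readr::write_csv(syn$vision, paths[["vision"]], na = "")
  ms <- syn$milestones
  ms$age_months <- ifelse(ms$never_observed, "never",
                          format(ms$age_months, trim = TRUE))
  readr::write_csv(ms[c("child_id", "milestone", "age_months")],
                   paths[["milestones"]], na = "")
  gt <- syn$ground_truth
  jsonlite::write_json(
    list(
      quantiles = gt$quantiles,
      site_effects = as.data.frame(gt$site_effects),
      target_between_share = gt$target_between_share,
      planted_exclusions = gt$planted_exclusions,
      seed = syn$seed
    ),
    paths[["ground_truth"]], auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(paths)
}
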