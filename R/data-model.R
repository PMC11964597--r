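# Domain tables and delimited-text I/O.
#
# All stages exchange plain tibbles:
#   subjects    : subject_id, age_y, pregnant
#   recalls     : subject_id, recall_day, food_id, amount_g
#   composition : food_id, name, mddw_group, is_injera, teff_type,
#                 teff_proportion, nutrient, content_ug_per_100g
# Amounts are grams of food as consumed (fresh basis); nutrient contents are
# ug per 100 g fresh basis, so the two never mix dry/fresh bases.

#' The 15 MDD-W food groups
#'
#' The Minimum Dietary Diversity for Women classification: 10 main food
#' groups plus 5 additional ones, used for descriptive dietary-pattern
#' summaries.
#'
#' @return Character vector of 15 group identifiers.
#' @export
mddw_groups <- function() {
  c(
    "grains_roots_tubers_plantains",
    "pulses",
    "nuts_seeds",
    "milk_products",
    "meat_poultry_fish",
    "eggs",
    "dark_green_leafy_vegetables",
    "vitamin_a_fruits_vegetables",
    "other_vegetables",
    "other_fruits",
    "insects_small_protein",
    "red_palm_oil",
    "sweets",
    "condiments_seasonings",
    "beverages"
  )
}

#' Nutrients handled by the pipeline
#' @return Character vector.
#' @export
nutrients <- function() c("folate", "cobalamin")

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_format <- function(msg) abort(msg, class = "fermadequacy_format_error")
stop_validation <- function(msg) abort(msg, class = "fermadequacy_validation_error")

require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop_format(sprintf(
      "%s file is missing required column(s): %s",
      what, paste(missing, collapse = ", ")
    ))
  }
  invisible(df)
}

#' Validate a subjects table
#'
#' Checks uniqueness of `subject_id` and that ages fall in the
#' women-of-reproductive-age window the survey design implies.
#'
#' @param subjects Tibble with columns `subject_id`, `age_y`, `pregnant`.
#' @return The input, invisibly, if valid; otherwise an error.
#' @export
validate_subjects <- function(subjects) {
  require_columns(subjects, c("subject_id", "age_y", "pregnant"), "subjects")
  if (anyDuplicated(subjects$subject_id)) {
    dup <- subjects$subject_id[duplicated(subjects$subject_id)][1]
    stop_validation(sprintf("duplicate subject_id '%s'", dup))
  }
  bad <- which(!(subjects$age_y > 10 & subjects$age_y < 60))
  if (length(bad) > 0) {
    stop_validation(sprintf(
      "subject '%s': age_y = %g outside the (10, 60) survey window",
      subjects$subject_id[bad[1]], subjects$age_y[bad[1]]
    ))
  }
  if (!is.logical(subjects$pregnant)) {
    stop_validation("column 'pregnant' must be logical")
  }
  invisible(subjects)
}

#' Validate a recall-line table against its subjects
#'
#' Enforces nonnegative amounts, recall days in \{1, 2\}, that every line
#' references a known subject, and that every subject contributes a day-1
#' recall (day 2 exists only for the repeat subsample).
#'
#' @param recalls Tibble with columns `subject_id`, `recall_day`, `food_id`,
#'   `amount_g`.
#' @param subjects Subjects table (see [validate_subjects()]).
#' @return The input recalls, invisibly, if valid.
#' @export
validate_recalls <- function(recalls, subjects) {
  require_columns(recalls, c("subject_id", "recall_day", "food_id", "amount_g"), "recalls")
  bad <- which(!(recalls$amount_g >= 0) | !is.finite(recalls$amount_g))
  if (length(bad) > 0) {
    stop_validation(sprintf(
      "row %d: amount_g = %g is negative or non-finite", bad[1], recalls$amount_g[bad[1]]
    ))
  }
  bad <- which(!recalls$recall_day %in% c(1L, 2L))
  if (length(bad) > 0) {
    stop_validation(sprintf(
      "row %d: recall_day = %s is not 1 or 2", bad[1], recalls$recall_day[bad[1]]
    ))
  }
  unknown <- setdiff(recalls$subject_id, subjects$subject_id)
  if (length(unknown) > 0) {
    stop_validation(sprintf("recall lines reference unknown subject '%s'", unknown[1]))
  }
  with_lines <- unique(recalls$subject_id)
  day1 <- unique(recalls$subject_id[recalls$recall_day == 1L])
  no_day1 <- setdiff(with_lines, day1)
  if (length(no_day1) > 0) {
    stop_validation(sprintf("subject '%s' has recall lines but no day-1 recall", no_day1[1]))
  }
  invisible(recalls)
}

#' Validate a composition table
#'
#' One record per (food, nutrient) key, nonnegative contents, and the injera
#' consistency rule: injera rows must carry a teff type and a blend
#' proportion in \{0.25, 0.5, 0.75, 1\}.
#'
#' @param composition Composition tibble.
#' @return The input, invisibly, if valid.
#' @export
validate_composition <- function(composition) {
  require_columns(
    composition,
    c("food_id", "name", "mddw_group", "is_injera", "teff_type",
      "teff_proportion", "nutrient", "content_ug_per_100g"),
    "composition"
  )
  key <- paste(composition$food_id, composition$nutrient, sep = "\r")
  if (anyDuplicated(key)) {
    d <- composition[duplicated(key), ][1, ]
    stop_validation(sprintf(
      "duplicate composition record for food '%s', nutrient '%s'", d$food_id, d$nutrient
    ))
  }
  bad <- which(!(composition$content_ug_per_100g >= 0))
  if (length(bad) > 0) {
    stop_validation(sprintf(
      "row %d: content_ug_per_100g = %g is negative",
      bad[1], composition$content_ug_per_100g[bad[1]]
    ))
  }
  if (!all(composition$nutrient %in% nutrients())) {
    stop_validation(sprintf(
      "unknown nutrient '%s'", setdiff(composition$nutrient, nutrients())[1]
    ))
  }
  if (!all(composition$mddw_group %in% mddw_groups())) {
    stop_validation(sprintf(
      "unknown MDD-W group '%s'", setdiff(composition$mddw_group, mddw_groups())[1]
    ))
  }
  inj <- composition[composition$is_injera, ]
  if (nrow(inj) > 0) {
    if (any(!inj$teff_type %in% c("red", "white"))) {
      stop_validation("injera records must have teff_type 'red' or 'white'")
    }
    if (any(!inj$teff_proportion %in% c(0.25, 0.5, 0.75, 1))) {
      stop_validation("injera records must have teff_proportion in {0.25, 0.5, 0.75, 1}")
    }
  }
  invisible(composition)
}

#' Read a 24-h recall file
#'
#' The file is comma-separated UTF-8 with a mandatory header and one row per
#' food consumption event; subject attributes (age, pregnancy) are
#' denormalized onto every row. `pregnant` is serialized as 0/1.
#'
#' @param path Path to a recalls CSV with columns `subject_id`, `age_y`,
#'   `pregnant`, `recall_day`, `food_id`, `amount_g`.
#' @return List with `recalls` (tibble of consumption lines, row order
#'   preserved) and `subjects` (one row per subject).
#' @export
read_recalls <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  require_columns(
    df, c("subject_id", "age_y", "pregnant", "recall_day", "food_id", "amount_g"),
    "recalls"
  )
  df <- df %>%
    mutate(
      subject_id = as.character(.data$subject_id),
      age_y = as.numeric(.data$age_y),
      pregnant = as.integer(.data$pregnant) == 1L,
      recall_day = as.integer(.data$recall_day),
      food_id = as.character(.data$food_id),
      amount_g = as.numeric(.data$amount_g)
    )
  subjects <- df %>%
    distinct(.data$subject_id, .data$age_y, .data$pregnant)
  if (anyDuplicated(subjects$subject_id)) {
    dup <- subjects$subject_id[duplicated(subjects$subject_id)][1]
    stop_validation(sprintf(
      "subject '%s' has inconsistent age/pregnancy attributes across rows", dup
    ))
  }
  recalls <- df %>% select("subject_id", "recall_day", "food_id", "amount_g")
  validate_subjects(subjects)
  validate_recalls(recalls, subjects)
  list(recalls = recalls, subjects = subjects)
}

#' Write a 24-h recall file
#'
#' Inverse of [read_recalls()]; writing the same records twice yields
#' byte-identical files.
#'
#' @param recalls Recall-line tibble.
#' @param subjects Subjects tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_recalls <- function(recalls, subjects, path) {
  validate_subjects(subjects)
  validate_recalls(recalls, subjects)
  out <- recalls %>%
    left_join(subjects, by = "subject_id") %>%
    mutate(pregnant = as.integer(.data$pregnant)) %>%
    select("subject_id", "age_y", "pregnant", "recall_day", "food_id", "amount_g")
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Read a food composition table
#'
#' @param path Path to a composition CSV with columns `food_id`, `name`,
#'   `mddw_group`, `is_injera`, `teff_type`, `teff_proportion`, `nutrient`,
#'   `content_ug_per_100g`. `is_injera` is serialized as 0/1;
#'   `teff_type`/`teff_proportion` are empty for non-injera foods.
#' @return Composition tibble with exactly one record per (food, nutrient).
#' @export
read_composition <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  require_columns(
    df, c("food_id", "name", "mddw_group", "is_injera", "teff_type",
          "teff_proportion", "nutrient", "content_ug_per_100g"),
    "composition"
  )
  df <- df %>%
    mutate(
      food_id = as.character(.data$food_id),
      name = as.character(.data$name),
      mddw_group = as.character(.data$mddw_group),
      is_injera = as.integer(.data$is_injera) == 1L,
      teff_type = ifelse(is.na(.data$teff_type) | .data$teff_type == "",
                         "none", as.character(.data$teff_type)),
      teff_proportion = as.numeric(.data$teff_proportion),
      nutrient = as.character(.data$nutrient),
      content_ug_per_100g = as.numeric(.data$content_ug_per_100g)
    )
  validate_composition(df)
  df
}

#' Write a food composition table
#'
#' @param composition Composition tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_composition <- function(composition, path) {
  validate_composition(composition)
  out <- composition %>%
    mutate(
      is_injera = as.integer(.data$is_injera),
      teff_type = ifelse(.data$teff_type == "none", NA_character_, .data$teff_type)
    )
  readr::write_csv(out, path, na = "", progress = FALSE)
  invisible(path)
}
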