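# Adequacy statistics: EAR cut-point prevalence of inadequacy and the
# per-individual probability of adequacy, plus descriptive food-group
# summaries.

#' Harmonized requirement specifications
#'
#' Estimated Average Requirements for women of reproductive age: folate
#' 250 (nonpregnant) / 520 (pregnant) ug/d, cobalamin 2.0 / 2.2 ug/d. The
#' requirement distribution is Normal(EAR, (cv * EAR)^2); `cv = 0.10` is the
#' conventional assumption behind the EAR cut-point method and can be
#' overridden.
#'
#' @param cv Requirement-distribution coefficient of variation, in (0, 0.5).
#' @return Tibble `nutrient`, `group`, `ear_ug`, `cv`.
#' @export
default_requirements <- function(cv = 0.10) {
  if (!(cv > 0 && cv < 0.5)) stop_validation("requirement cv must be in (0, 0.5)")
  tibble(
    nutrient = rep(nutrients(), each = 2),
    group = rep(c("nonpregnant", "pregnant"), 2),
    ear_ug = c(250, 520, 2.0, 2.2),
    cv = cv
  )
}

#' Read requirement specifications from YAML
#'
#' @param path YAML file: a list of `{nutrient, group, ear_ug, cv}` entries.
#' @return Requirements tibble (see [default_requirements()]).
#' @export
read_requirements <- function(path) {
  raw <- yaml::read_yaml(path)
  out <- purrr::map_dfr(raw, function(r) {
    tibble(nutrient = r$nutrient, group = r$group,
           ear_ug = as.numeric(r$ear_ug), cv = as.numeric(r$cv %||% 0.10))
  })
  if (any(out$ear_ug <= 0)) stop_validation("ear_ug must be positive")
  if (any(!(out$cv > 0 & out$cv < 0.5))) stop_validation("cv must be in (0, 0.5)")
  out
}

get_requirement <- function(requirements, nutrient, group) {
  r <- requirements[requirements$nutrient == nutrient & requirements$group == group, ]
  if (nrow(r) != 1) {
    stop_validation(sprintf("no unique requirement for %s / %s", nutrient, group))
  }
  r
}

#' Prevalence of inadequate intake (EAR cut-point method)
#'
#' The fraction of individuals whose usual intake falls strictly below the
#' EAR, as a percentage. Ties at exactly the EAR count as adequate.
#'
#' @param usual_intakes Numeric vector of usual intakes (ug/d).
#' @param spec One row of a requirements tibble (needs `ear_ug`).
#' @return Percentage in \[0, 100\].
#' @export
prevalence_inadequacy <- function(usual_intakes, spec) {
  if (length(usual_intakes) == 0) stop_validation("empty group")
  100 * mean(usual_intakes < spec$ear_ug)
}

#' Per-individual probability of adequacy
#'
#' With requirements distributed Normal(EAR, (cv * EAR)^2), the probability
#' that an individual's usual intake `u` exceeds her requirement is
#' `pnorm((u - EAR) / (cv * EAR))`. The group statistic is the mean (and SD)
#' of this quantity over individuals.
#'
#' @param usual_intake Numeric vector of usual intakes (ug/d).
#' @param spec One row of a requirements tibble (needs `ear_ug`, `cv`).
#' @return Probabilities in \[0, 1\], one per intake.
#' @export
probability_of_adequacy <- function(usual_intake, spec) {
  if (any(!is.finite(usual_intake))) stop_validation("non-finite usual intake")
  pnorm((usual_intake - spec$ear_ug) / (spec$cv * spec$ear_ug))
}

#' Summarize adequacy for one nutrient x scenario x group cell
#'
#' Assembles the report cell: mean (SD) usual intake, mean (SD) probability
#' of adequacy, and prevalence of inadequacy. SDs use the n-1 denominator;
#' a single-subject group gets SD 0 by convention (with a warning).
#'
#' @param usual_intakes Numeric vector of usual intakes for the group.
#' @param spec One row of a requirements tibble.
#' @param nutrient,scenario,group Labels for the output row.
#' @return One-row tibble (an adequacy result).
#' @export
summarize_group <- function(usual_intakes, spec, nutrient, scenario, group) {
  n <- length(usual_intakes)
  if (n == 0) stop_validation("empty group")
  pa <- probability_of_adequacy(usual_intakes, spec)
  if (n < 2) warning("single-subject group: SDs reported as 0 by convention")
  sd0 <- function(x) if (length(x) < 2) 0 else sd(x)
  tibble(
    nutrient = nutrient,
    scenario = scenario,
    group = group,
    n = n,
    mean_usual = mean(usual_intakes),
    sd_usual = sd0(usual_intakes),
    mean_pa = mean(pa),
    sd_pa = sd0(pa),
    prevalence_inadequacy = prevalence_inadequacy(usual_intakes, spec)
  )
}

#' Descriptive food-group summary
#'
#' Mean day-1 consumption (g/d) of each of the 15 MDD-W food groups by
#' pregnancy status, computed directly from observed recall values (all
#' subjects in the denominator, including non-consumers; all 15 groups
#' reported, zero when unconsumed).
#'
#' @param recalls Recall-line tibble.
#' @param subjects Subjects tibble.
#' @param composition Composition tibble supplying the food -> MDD-W group map.
#' @return Tibble `mddw_group`, `group`, `mean_g`, `sd_g`.
#' @export
summarize_food_groups <- function(recalls, subjects, composition) {
  foods <- composition %>% distinct(.data$food_id, .data$mddw_group)
  unknown <- setdiff(unique(recalls$food_id), foods$food_id)
  if (length(unknown) > 0) {
    stop_validation(sprintf("unknown food_id '%s' in recalls", unknown[1]))
  }
  day1 <- recalls %>%
    filter(.data$recall_day == 1L) %>%
    left_join(foods, by = "food_id") %>%
    group_by(.data$subject_id, .data$mddw_group) %>%
    summarise(grams = sum(.data$amount_g), .groups = "drop")
  tidyr::expand_grid(
    subject_id = subjects$subject_id, mddw_group = mddw_groups()
  ) %>%
    left_join(day1, by = c("subject_id", "mddw_group")) %>%
    mutate(grams = ifelse(is.na(.data$grams), 0, .data$grams)) %>%
    left_join(subjects %>% select("subject_id", "pregnant"), by = "subject_id") %>%
    mutate(group = ifelse(.data$pregnant, "pregnant", "nonpregnant")) %>%
    group_by(.data$mddw_group, .data$group) %>%
    summarise(mean_g = mean(.data$grams),
              sd_g = if (dplyr::n() < 2) 0 else sd(.data$grams),
              .groups = "drop")
}
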