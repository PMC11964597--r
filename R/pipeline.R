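# End-to-end orchestration: simulate or load recall data, apply each
# fermentation scenario, compute daily intakes, fit the usual-intake model
# (pooled over pregnancy groups, with pregnancy as a covariate), and
# summarize adequacy per pregnancy group.

#' Build a pipeline run configuration
#'
#' @param recalls Path to a recalls CSV, or `NULL` to simulate.
#' @param simulate List with `n_nonpregnant`, `n_pregnant`,
#'   `repeat_nonpregnant`, `repeat_pregnant`, `seed`; used when `recalls` is
#'   `NULL`. Defaults mirror the survey design (164 + 159 women, repeat
#'   recalls for 25 + 41).
#' @param composition Path to a composition CSV, or `"default"` for the
#'   bundled table.
#' @param scenarios Character vector of built-in scenario names, or a list of
#'   `scenario` objects. At least one.
#' @param nutrients Nutrients to analyze. At least one.
#' @param requirements `"harmonized-defaults"` or a path to a requirements
#'   YAML file.
#' @param requirement_cv Optional override of the requirement-distribution CV.
#' @param shrinkage `"sqrt"` (default) or `"blup"` (see [fit_usual_intake()]).
#' @param fit_per_group Fit the usual-intake model separately per pregnancy
#'   group instead of pooled with a pregnancy covariate.
#' @param out_dir Optional directory for the report and run manifest.
#' @return A `run_config` list.
#' @export
run_config <- function(recalls = NULL,
                       simulate = list(n_nonpregnant = 164, n_pregnant = 159,
                                       repeat_nonpregnant = 25, repeat_pregnant = 41,
                                       seed = 1),
                       composition = "default",
                       scenarios = names(builtin_scenarios()),
                       nutrients = c("folate", "cobalamin"),
                       requirements = "harmonized-defaults",
                       requirement_cv = NULL,
                       shrinkage = "sqrt",
                       fit_per_group = FALSE,
                       out_dir = NULL) {
  if (length(scenarios) == 0) stop_validation("at least one scenario required")
  if (length(nutrients) == 0) stop_validation("at least one nutrient required")
  structure(
    list(recalls = recalls, simulate = simulate, composition = composition,
         scenarios = scenarios, nutrients = nutrients,
         requirements = requirements, requirement_cv = requirement_cv,
         shrinkage = shrinkage, fit_per_group = fit_per_group,
         out_dir = out_dir),
    class = "run_config"
  )
}

resolve_scenarios <- function(spec) {
  if (is.character(spec)) {
    all <- builtin_scenarios()
    unknown <- setdiff(spec, names(all))
    if (length(unknown) > 0) {
      stop_validation(sprintf("unknown built-in scenario '%s'", unknown[1]))
    }
    all[spec]
  } else {
    stopifnot(all(purrr::map_lgl(spec, inherits, "scenario")))
    stats::setNames(spec, purrr::map_chr(spec, "name"))
  }
}

with_stage <- function(stage, scenario, nutrient, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("[scenario %s, nutrient %s, stage %s] %s",
                  scenario, nutrient, stage, conditionMessage(e)),
          class = "fermadequacy_pipeline_error", parent = e)
  })
}

#' Run the full adequacy pipeline
#'
#' For each nutrient x scenario (in configuration order): apply the scenario
#' to the composition table, compute per-subject-day intakes, fit the
#' usual-intake model, and summarize adequacy for the nonpregnant and
#' pregnant groups. When `out_dir` is set, writes `report.csv`,
#' `report.md` and a `manifest.json` recording the seed, package version and
#' configuration hash.
#'
#' @param config A `run_config` (see [run_config()]).
#' @param quiet Suppress per-stage progress messages.
#' @return Tibble of adequacy results, one row per
#'   nutrient x scenario x group.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (!quiet) message(sprintf(...))

  if (is.null(config$recalls)) {
    sim <- config$simulate
    subjects <- generate_population(sim$n_nonpregnant, sim$n_pregnant, sim$seed)
    gen <- generate_recalls(
      subjects,
      repeat_n_nonpregnant = sim$repeat_nonpregnant,
      repeat_n_pregnant = sim$repeat_pregnant,
      seed = sim$seed + 1
    )
    recalls <- gen$recalls
    say("simulated cohort: %d subjects, %d recall lines, %d with repeat recall",
        nrow(subjects), nrow(recalls), length(gen$repeat_subjects))
  } else {
    loaded <- read_recalls(config$recalls)
    recalls <- loaded$recalls
    subjects <- loaded$subjects
    say("loaded cohort: %d subjects, %d recall lines",
        nrow(subjects), nrow(recalls))
  }

  composition <- if (identical(config$composition, "default")) {
    default_composition()
  } else {
    read_composition(config$composition)
  }
  requirements <- if (identical(config$requirements, "harmonized-defaults")) {
    default_requirements()
  } else {
    read_requirements(config$requirements)
  }
  if (!is.null(config$requirement_cv)) {
    requirements$cv <- config$requirement_cv
  }
  scenarios <- resolve_scenarios(config$scenarios)
  days <- recall_days(recalls, subjects)
  groups <- list(nonpregnant = !subjects$pregnant, pregnant = subjects$pregnant)

  results <- list()
  for (nut in config$nutrients) {
    for (sc in scenarios) {
      tab <- with_stage("apply_scenario", sc$name, nut,
                        apply_scenario(composition, sc))
      di <- with_stage("compute_daily_intakes", sc$name, nut,
                       compute_daily_intakes(recalls, tab, nut, days = days))
      fits <- if (config$fit_per_group) {
        purrr::map(groups, function(sel) {
          sub <- subjects[sel, ]
          with_stage("fit_usual_intake", sc$name, nut,
                     fit_usual_intake(di %>% filter(.data$subject_id %in% sub$subject_id),
                                      sub, shrinkage = config$shrinkage))
        })
      } else {
        fit <- with_stage("fit_usual_intake", sc$name, nut,
                          fit_usual_intake(di, subjects, shrinkage = config$shrinkage))
        list(nonpregnant = fit, pregnant = fit)
      }
      say("fitted %s / %s: lambda = %.2f, %d subjects",
          nut, sc$name, fits[[1]]$params$lambda, fits[[1]]$n_subjects)
      for (grp in names(groups)) {
        sub_ids <- subjects$subject_id[groups[[grp]]]
        if (length(sub_ids) == 0) next
        u <- fits[[grp]]$usual_intakes %>%
          filter(.data$subject_id %in% sub_ids) %>%
          pull("usual_intake")
        spec <- get_requirement(requirements, nut, grp)
        results[[length(results) + 1]] <-
          with_stage("summarize_group", sc$name, nut,
                     summarize_group(u, spec, nut, sc$name, grp))
      }
    }
  }
  report <- bind_rows(results)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    render_report(report, "csv", file.path(config$out_dir, "report.csv"))
    render_report(report, "markdown", file.path(config$out_dir, "report.md"))
    manifest <- list(
      package_version = as.character(utils::packageVersion("fermadequacy")),
      seed = if (is.null(config$recalls)) config$simulate$seed else NULL,
      config_hash = rlang::hash(unclass(config)),
      n_subjects = nrow(subjects),
      n_recall_lines = nrow(recalls)
    )
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  report
}

format_sig3 <- function(x) signif(x, 3)

#' Render an adequacy report
#'
#' Writes the results table in the layout of the published summary: usual
#' intake mean (SD), probability of adequacy mean (SD), and prevalence of
#' inadequacy per nutrient x scenario x group. Intakes are reported to 3
#' significant figures, probabilities to 2 decimals, prevalences to 1
#' decimal. Output is deterministic: the same results produce byte-identical
#' files.
#'
#' @param results Results tibble from [run_pipeline()].
#' @param format `"csv"` (numeric columns, machine-readable) or
#'   `"markdown"` (pretty "mean (SD)" cells).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
render_report <- function(results, format = c("csv", "markdown"), path) {
  format <- match.arg(format)
  if (nrow(results) == 0) stop_validation("empty results")
  if (format == "csv") {
    out <- results %>%
      mutate(
        mean_usual = format_sig3(.data$mean_usual),
        sd_usual = format_sig3(.data$sd_usual),
        mean_pa = round(.data$mean_pa, 2),
        sd_pa = round(.data$sd_pa, 2),
        prevalence_inadequacy = round(.data$prevalence_inadequacy, 1)
      )
    readr::write_csv(out, path, progress = FALSE)
  } else {
    lines <- c(
      "| Nutrient | Scenario | Group | n | Usual intake (ug/d) | Probability of adequacy | Prevalence of inadequacy (%) |",
      "|---|---|---|---|---|---|---|",
      purrr::pmap_chr(results, function(nutrient, scenario, group, n, mean_usual,
                                        sd_usual, mean_pa, sd_pa,
                                        prevalence_inadequacy, ...) {
        sprintf("| %s | %s | %s | %d | %g (%g) | %.2f (%.2f) | %.1f |",
                nutrient, scenario, group, n,
                format_sig3(mean_usual), format_sig3(sd_usual),
                mean_pa, sd_pa, prevalence_inadequacy)
      })
    )
    writeLines(lines, path)
  }
  invisible(path)
}
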