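# Synthetic cohort and recall generator.
#
# Emulates the statistical structure of a rural Ethiopian dietary survey of
# women of reproductive age: ~160 women per pregnancy group, a second 24-h
# recall for a small subsample, a plant-based diet dominated by injera and
# other grains, and near-zero animal-source intakes. Every generated cohort
# carries ground-truth usual intakes so estimator recovery can be tested.
#
# All randomness goes through R's default Mersenne-Twister generator; a given
# seed reproduces a cohort exactly.

with_rng_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed)) {
    stop_validation("seed must be a single integer")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister")
  expr
}

# lognormal parameters for a target arithmetic mean m and coefficient of
# variation cv: sdlog^2 = log(1 + cv^2), meanlog = log(m) - sdlog^2 / 2
lnorm_params <- function(mean, cv) {
  sdlog <- sqrt(log(1 + cv^2))
  list(meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

#' Construct a food consumption profile
#'
#' A profile drives the generator for one food: a person-level Bernoulli
#' consumer indicator (fixed across days, matching the habitual-consumer
#' assumption of the usual-intake model), a lognormal person-level mean
#' amount among consumers, and lognormal day-to-day variation around that
#' mean.
#'
#' @param food_id Food identifier; for foods with `variants`, the identifier
#'   of the abstract food (each consumer is assigned one concrete variant).
#' @param consumer_probability Probability a woman is a habitual consumer.
#' @param mean_amount_g Mean amount (g/d) among consumers.
#' @param between_cv Coefficient of variation of the person-level mean.
#' @param within_cv Coefficient of variation of day amounts around the
#'   person-level mean.
#' @param variants Optional character vector of concrete variant `food_id`s
#'   (e.g. injera by teff type and blend); a consumer is assigned one
#'   uniformly at random, fixed across days.
#' @return One-row tibble (variants as a list-column).
#' @export
food_profile <- function(food_id, consumer_probability, mean_amount_g,
                         between_cv = 0.35, within_cv = 0.5,
                         variants = character(0)) {
  if (consumer_probability < 0 || consumer_probability > 1) {
    stop_validation("consumer_probability must be in [0, 1]")
  }
  if (mean_amount_g <= 0) stop_validation("mean_amount_g must be positive")
  if (between_cv < 0 || within_cv < 0) stop_validation("CVs must be nonnegative")
  tibble(
    food_id = food_id,
    consumer_probability = consumer_probability,
    mean_amount_g = mean_amount_g,
    between_cv = between_cv,
    within_cv = within_cv,
    variants = list(variants)
  )
}

#' Default food consumption profiles
#'
#' Calibrated so a large generated cohort reproduces the survey's printed
#' food-group means: grains/white roots/tubers/plantains 497 g/d (of which
#' injera 170 g/d overall, 442 g/d among the 38% of consumers), dark green
#' leafy vegetables 235 g/d, other vegetables 100 g/d, pulses 69 g/d, milk
#' products 15.2 g/d, and meat/poultry/fish 3.5 g/d. Between- and
#' within-person CVs default to 0.35 and 0.5, typical magnitudes for
#' repeated 24-h recalls.
#'
#' @return Tibble of profiles, one row per food (see [food_profile()]).
#' @export
default_profiles <- function() {
  bind_rows(
    food_profile("injera", 0.38, 442,
                 variants = injera_variant_ids()),
    food_profile("maize_porridge", 0.95, 329 / 0.95),
    food_profile("kale_gomen", 0.90, 235 / 0.90),
    food_profile("mixed_vegetables", 0.85, 100 / 0.85),
    food_profile("shiro_wot", 0.80, 69 / 0.80),
    food_profile("milk", 0.25, 15.2 / 0.25),
    food_profile("beef", 0.10, 3.5 / 0.10)
  )
}

injera_variant_ids <- function() {
  grid <- expand.grid(
    teff_type = c("red", "white"), prop = c(0.25, 0.5, 0.75, 1),
    stringsAsFactors = FALSE
  )
  sprintf("injera_%s_%03d", grid$teff_type, as.integer(grid$prop * 100))
}

#' Default food composition table
#'
#' Folate and cobalamin (ug/100 g fresh basis) for the bundled foods. The
#' eight injera variants (red/white teff x 25/50/75/100% teff blend) span
#' 0-18 ug folate/100 g, the range of the unfermented-basis survey values.
#' All plant foods have cobalamin 0, reflecting the composition-table
#' convention the scenarios challenge; milk and meat carry small positive
#' cobalamin contents of Kenyan food-composition-table magnitude. Other
#' plant foods' folate is calibrated so the unmodified table yields a usual
#' folate intake near 210 ug/d.
#'
#' @return Composition tibble (see [read_composition()] for the schema).
#' @export
default_composition <- function() {
  grid <- expand.grid(
    teff_type = c("red", "white"), prop = c(0.25, 0.5, 0.75, 1),
    stringsAsFactors = FALSE
  )
  # red teff injera richer in folate; white 25% blend anchors the 0 end
  inj_folate <- ifelse(grid$teff_type == "red", 18 * grid$prop, 18 * grid$prop - 4.5)
  inj <- tibble(
    food_id = injera_variant_ids(),
    name = sprintf("Injera, %s teff, %d%% teff flour",
                   grid$teff_type, as.integer(grid$prop * 100)),
    mddw_group = "grains_roots_tubers_plantains",
    is_injera = TRUE,
    teff_type = grid$teff_type,
    teff_proportion = grid$prop,
    folate = inj_folate,
    cobalamin = 0
  )
  other <- tibble(
    food_id = c("maize_porridge", "kale_gomen", "mixed_vegetables",
                "shiro_wot", "milk", "beef"),
    name = c("Maize porridge", "Kale (gomen), cooked", "Mixed vegetables, cooked",
             "Shiro wot (chickpea stew)", "Cow milk, whole", "Beef, cooked"),
    mddw_group = c("grains_roots_tubers_plantains", "dark_green_leafy_vegetables",
                   "other_vegetables", "pulses", "milk_products", "meat_poultry_fish"),
    is_injera = FALSE,
    teff_type = "none",
    teff_proportion = NA_real_,
    folate = c(20, 25, 25, 70, 5, 8),
    cobalamin = c(0, 0, 0, 0, 0.4, 1.5)
  )
  out <- bind_rows(inj, other) %>%
    tidyr::pivot_longer(c("folate", "cobalamin"),
                        names_to = "nutrient", values_to = "content_ug_per_100g")
  validate_composition(out)
  out
}

#' Generate a synthetic cohort of women
#'
#' Ages are drawn from a Normal(29.8, 6) truncated to 15-49 years, matching
#' the survey's women-of-reproductive-age design and printed mean age.
#'
#' @param n_nonpregnant,n_pregnant Group sizes (nonnegative).
#' @param seed Integer seed; identical seeds give identical cohorts.
#' @return Subjects tibble (`subject_id`, `age_y`, `pregnant`).
#' @export
generate_population <- function(n_nonpregnant, n_pregnant, seed) {
  if (n_nonpregnant < 0 || n_pregnant < 0) stop_validation("counts must be nonnegative")
  n <- n_nonpregnant + n_pregnant
  with_rng_seed(seed, {
    ages <- numeric(0)
    while (length(ages) < n) {
      draw <- rnorm(max(n, 16), mean = 29.8, sd = 6)
      ages <- c(ages, draw[draw >= 15 & draw <= 49])
    }
    ages <- ages[seq_len(n)]
    tibble(
      subject_id = sprintf("S%04d", seq_len(n)),
      age_y = round(ages, 1),
      pregnant = rep(c(FALSE, TRUE), c(n_nonpregnant, n_pregnant))
    )
  })
}

#' Generate 24-h recall data with known ground truth
#'
#' For each subject and food profile, consumer status is a person-level
#' Bernoulli draw fixed across days; consumers receive a lognormal
#' person-level mean amount, and each recall day an independent lognormal
#' amount around it. Foods with variants (injera) assign each consumer one
#' variant uniformly at random, fixed across days. Day-2 recalls exist only
#' for a simple random subsample of the stated sizes per pregnancy group.
#'
#' The returned `truth` table gives each subject's exact conditional
#' expected daily nutrient intake given her person-level draws: the sum over
#' consumed foods of person-level mean amount times nutrient content per
#' gram. `person_params` exposes the person-level state (assigned variant,
#' person mean, within-person CV) for simulation-based checks.
#'
#' @param subjects Subjects tibble (see [generate_population()]).
#' @param profiles Food profiles (see [default_profiles()]).
#' @param repeat_n_nonpregnant,repeat_n_pregnant Sizes of the repeat-recall
#'   subsample per group; must not exceed the group sizes.
#' @param seed Integer seed.
#' @param composition Composition table used to compute ground-truth nutrient
#'   intakes; defaults to [default_composition()].
#' @return List with `recalls`, `truth` (subject x nutrient
#'   `true_usual_intake`), `person_params`, and `repeat_subjects` (ids with a
#'   day-2 recall).
#' @export
generate_recalls <- function(subjects, profiles = default_profiles(),
                             repeat_n_nonpregnant = 25, repeat_n_pregnant = 41,
                             seed = 1, composition = default_composition()) {
  validate_subjects(subjects)
  n_np <- sum(!subjects$pregnant)
  n_p <- sum(subjects$pregnant)
  if (repeat_n_nonpregnant > n_np || repeat_n_pregnant > n_p) {
    stop_validation("repeat subsample size exceeds group size")
  }
  with_rng_seed(seed, {
    repeat_ids <- c(
      sample(subjects$subject_id[!subjects$pregnant], repeat_n_nonpregnant),
      sample(subjects$subject_id[subjects$pregnant], repeat_n_pregnant)
    )

    grid <- tidyr::expand_grid(
      s_idx = seq_len(nrow(subjects)),
      f_idx = seq_len(nrow(profiles))
    )
    grid$subject_id <- subjects$subject_id[grid$s_idx]
    prof <- profiles[grid$f_idx, ]
    n_cell <- nrow(grid)

    consumer <- rbinom(n_cell, 1, prof$consumer_probability) == 1
    bl <- lnorm_params(prof$mean_amount_g, prof$between_cv)
    person_mean <- rlnorm(n_cell, bl$meanlog, bl$sdlog)
    variant_u <- runif(n_cell)
    assigned <- purrr::map2_chr(prof$variants, variant_u, function(v, u) {
      if (length(v) == 0) NA_character_ else v[floor(u * length(v)) + 1]
    })
    assigned <- ifelse(is.na(assigned), prof$food_id, assigned)

    wl <- lnorm_params(person_mean, prof$within_cv)
    amount1 <- rlnorm(n_cell, wl$meanlog, wl$sdlog)
    amount2 <- rlnorm(n_cell, wl$meanlog, wl$sdlog)

    keep <- consumer
    day2 <- grid$subject_id %in% repeat_ids
    recalls <- bind_rows(
      tibble(s_idx = grid$s_idx[keep], f_idx = grid$f_idx[keep],
             subject_id = grid$subject_id[keep], recall_day = 1L,
             food_id = assigned[keep], amount_g = amount1[keep]),
      tibble(s_idx = grid$s_idx[keep & day2], f_idx = grid$f_idx[keep & day2],
             subject_id = grid$subject_id[keep & day2], recall_day = 2L,
             food_id = assigned[keep & day2], amount_g = amount2[keep & day2])
    ) %>%
      arrange(.data$s_idx, .data$recall_day, .data$f_idx) %>%
      select("subject_id", "recall_day", "food_id", "amount_g")

    person_params <- tibble(
      subject_id = grid$subject_id[keep],
      food_id = assigned[keep],
      person_mean_g = person_mean[keep],
      within_cv = prof$within_cv[keep]
    )

    content <- composition %>% select("food_id", "nutrient", "content_ug_per_100g")
    truth <- tidyr::expand_grid(
      subject_id = subjects$subject_id, nutrient = nutrients()
    ) %>%
      left_join(
        person_params %>%
          left_join(content, by = "food_id", relationship = "many-to-many") %>%
          group_by(.data$subject_id, .data$nutrient) %>%
          summarise(
            true_usual_intake = sum(.data$person_mean_g * .data$content_ug_per_100g / 100),
            .groups = "drop"
          ),
        by = c("subject_id", "nutrient")
      ) %>%
      mutate(true_usual_intake = ifelse(is.na(.data$true_usual_intake), 0,
                                        .data$true_usual_intake))

    list(
      recalls = recalls,
      truth = truth,
      person_params = person_params,
      repeat_subjects = repeat_ids
    )
  })
}
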