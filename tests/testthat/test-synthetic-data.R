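test_that("generate_population matches the survey design", {
  subj <- generate_population(164, 159, seed = 1)
  expect_equal(nrow(subj), 323)
  expect_equal(sum(subj$pregnant), 159)
  expect_false(anyDuplicated(subj$subject_id) > 0)
  expect_true(all(subj$age_y >= 15 & subj$age_y <= 49))
  # cohort mean age near the printed 29.8 y (check at large n to beat noise)
  big <- generate_population(4000, 0, seed = 2)
  expect_lt(abs(mean(big$age_y) - 29.8), 0.5)
})

test_that("generation is deterministic given the seed and handles edge counts", {
  expect_identical(generate_population(20, 20, 5), generate_population(20, 20, 5))
  expect_equal(nrow(generate_population(0, 0, 1)), 0)
  expect_error(generate_population(-1, 0, 1), "nonnegative")

  subj <- generate_population(30, 30, 3)
  g1 <- generate_recalls(subj, repeat_n_nonpregnant = 5, repeat_n_pregnant = 5, seed = 9)
  g2 <- generate_recalls(subj, repeat_n_nonpregnant = 5, repeat_n_pregnant = 5, seed = 9)
  expect_identical(g1$recalls, g2$recalls)
  expect_identical(g1$truth, g2$truth)
})

test_that("the repeat-recall design is honoured", {
  subj <- generate_population(164, 159, seed = 4)
  gen <- generate_recalls(subj, repeat_n_nonpregnant = 25, repeat_n_pregnant = 41, seed = 5)
  day2 <- unique(gen$recalls$subject_id[gen$recalls$recall_day == 2L])
  expect_setequal(day2, intersect(gen$repeat_subjects, unique(gen$recalls$subject_id)))
  expect_equal(length(gen$repeat_subjects), 66)
  preg <- subj$subject_id[subj$pregnant]
  expect_equal(sum(gen$repeat_subjects %in% preg), 41)
  expect_error(
    generate_recalls(subj, repeat_n_nonpregnant = 200, repeat_n_pregnant = 0, seed = 1),
    "exceeds group size"
  )
})

test_that("injera consumption calibration matches the survey pattern", {
  subj <- generate_population(164, 159, seed = 10)
  gen <- generate_recalls(subj, seed = 11)
  inj_day1 <- gen$recalls %>%
    dplyr::filter(recall_day == 1L, grepl("^injera", food_id))
  overall_mean <- sum(inj_day1$amount_g) / nrow(subj)
  expect_lt(abs(overall_mean - 168) / 168, 0.10)

  # consumer fraction converges to the profile probability in a large cohort
  big <- generate_population(10000, 0, seed = 12)
  gen_big <- generate_recalls(big, repeat_n_nonpregnant = 0, repeat_n_pregnant = 0,
                              seed = 13)
  frac <- length(unique(gen_big$recalls$subject_id[grepl("^injera", gen_big$recalls$food_id)])) / 10000
  expect_lt(abs(frac - 0.38), 0.02)
})

test_that("degenerate noise gives identical recall days", {
  subj <- generate_population(10, 10, seed = 20)
  prof <- food_profile("maize_porridge", consumer_probability = 1,
                       mean_amount_g = 300, between_cv = 0.3, within_cv = 0)
  gen <- generate_recalls(subj, profiles = prof,
                          repeat_n_nonpregnant = 10, repeat_n_pregnant = 10, seed = 21)
  wide <- tidyr::pivot_wider(gen$recalls, names_from = recall_day,
                             values_from = amount_g)
  expect_equal(wide$`1`, wide$`2`)
})

test_that("truth records equal the long-run mean of simulated days", {
  # independent Monte-Carlo oracle: redraw 1e4 day amounts from each
  # subject's person-level state and compare the empirical mean intake
  # with the recorded ground truth
  subj <- generate_population(3, 2, seed = 30)
  gen <- generate_recalls(subj, repeat_n_nonpregnant = 1, repeat_n_pregnant = 1, seed = 31)
  comp <- default_composition()
  content <- comp %>% dplyr::filter(nutrient == "folate")
  set.seed(99)
  for (sid in subj$subject_id) {
    pp <- gen$person_params %>% dplyr::filter(subject_id == sid)
    truth <- gen$truth %>%
      dplyr::filter(subject_id == sid, nutrient == "folate") %>%
      dplyr::pull(true_usual_intake)
    if (nrow(pp) == 0) {
      expect_equal(truth, 0)
      next
    }
    days <- replicate(1e4, {
      sdlog <- sqrt(log(1 + pp$within_cv^2))
      amt <- rlnorm(nrow(pp), log(pp$person_mean_g) - sdlog^2 / 2, sdlog)
      sum(amt * content$content_ug_per_100g[match(pp$food_id, content$food_id)] / 100)
    })
    expect_lt(abs(mean(days) - truth) / truth, 0.01)
  }
})

test_that("default composition encodes the fermentation-relevant structure", {
  comp <- default_composition()
  inj_folate <- comp %>% dplyr::filter(is_injera, nutrient == "folate")
  expect_equal(nrow(inj_folate), 8)
  expect_true(all(inj_folate$content_ug_per_100g >= 0 &
                    inj_folate$content_ug_per_100g <= 18))
  plant_cob <- comp %>%
    dplyr::filter(!mddw_group %in% c("milk_products", "meat_poultry_fish"),
                  nutrient == "cobalamin")
  expect_true(all(plant_cob$content_ug_per_100g == 0))
  probs <- default_profiles()$consumer_probability
  expect_true(all(probs >= 0 & probs <= 1))
})

test_that("default profiles reproduce the printed food-group means", {
  subj <- generate_population(1500, 1500, seed = 40)
  gen <- generate_recalls(subj, repeat_n_nonpregnant = 0, repeat_n_pregnant = 0, seed = 41)
  fg <- summarize_food_groups(gen$recalls, subj, default_composition())
  grains <- fg %>% dplyr::filter(mddw_group == "grains_roots_tubers_plantains")
  expect_true(all(abs(grains$mean_g - 497) / 497 < 0.10))
  milk <- fg %>% dplyr::filter(mddw_group == "milk_products")
  expect_true(all(abs(milk$mean_g - 15.2) / 15.2 < 0.15))
  dglv <- fg %>% dplyr::filter(mddw_group == "dark_green_leafy_vegetables")
  expect_true(all(abs(dglv$mean_g - 235) / 235 < 0.10))
})
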