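# Shared fixtures, all built in code at test time.

tiny_subjects <- function() {
  tibble::tibble(
    subject_id = c("A", "B", "C", "D"),
    age_y = c(25, 32.5, 41, 19),
    pregnant = c(FALSE, TRUE, FALSE, TRUE)
  )
}

tiny_recalls <- function() {
  tibble::tibble(
    subject_id = c("A", "A", "B", "B", "C", "D"),
    recall_day = c(1L, 2L, 1L, 1L, 1L, 1L),
    food_id = c("injera_red_100", "injera_red_100", "kale_gomen",
                "milk", "shiro_wot", "beef"),
    amount_g = c(442, 300, 150, 60, 90, 35)
  )
}

# a small randomized-but-reproducible cohort for round-trip property tests
random_cohort <- function(seed) {
  subjects <- generate_population(8, 7, seed)
  gen <- generate_recalls(subjects,
                          repeat_n_nonpregnant = 3, repeat_n_pregnant = 2,
                          seed = seed + 500)
  list(subjects = subjects, recalls = gen$recalls, gen = gen)
}

expect_tables_equal <- function(a, b) {
  expect_equal(as.data.frame(a), as.data.frame(b), tolerance = 1e-12)
}
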