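bc <- function(lambda, shift = 0) {
  structure(list(lambda = lambda, shift = shift), class = "boxcox_params")
}

test_that("Box-Cox transform and inverse are exact inverses", {
  y <- c(0.5, 1, 7.3, 150, 4200)
  for (params in list(bc(0), bc(0.5), bc(-1.2), bc(1), bc(0.3, shift = 2))) {
    z <- boxcox_transform(y, params)
    expect_equal(boxcox_inverse(z, params), y, tolerance = 1e-10)
  }
  expect_error(boxcox_transform(c(-3, 1), bc(0.5)), "positive")
})

test_that("fit_boxcox recovers the generating transform", {
  set.seed(101)
  ln <- rlnorm(2000, meanlog = 2, sdlog = 0.7)
  expect_lt(abs(fit_boxcox(ln)$lambda), 0.1)

  # lambda is only weakly identified when the coefficient of variation is
  # small, so use a well-spread positive sample
  nm <- rnorm(5000, mean = 50, sd = 9)
  lam <- fit_boxcox(nm)$lambda
  expect_lt(abs(lam - 1), 0.2)
})

test_that("fit_boxcox agrees with an independent profile-likelihood oracle", {
  # MASS::boxcox profiles the same one-parameter likelihood (shift 0);
  # the two maximizers should agree to grid resolution
  set.seed(102)
  y <- rlnorm(500, 1.5, 0.5)^0.8
  ours <- fit_boxcox(y, shift_candidates = 0)
  m <- MASS::boxcox(y ~ 1, lambda = seq(-2, 2, 0.01), plotit = FALSE)
  expect_lt(abs(ours$lambda - m$x[which.max(m$y)]), 0.02)
})

test_that("fit_boxcox rejects degenerate inputs", {
  expect_error(fit_boxcox(rep(3, 20)), "degenerate")
  expect_error(fit_boxcox(c(1, 2, 3)), "at least 10")
  expect_error(fit_boxcox(c(0, seq_len(19)), shift_candidates = 0),
               "no shift candidate")
  zeros <- c(0, 0, seq_len(18))
  p <- fit_boxcox(zeros)  # default candidates handle zeros via a shift
  expect_gt(p$shift, 0)
})

test_that("variance components equal a one-way ANOVA oracle on a balanced fixture", {
  r <- c(0.3, -0.1, 1.2, 0.8, -0.5, -0.9, 0.05, 0.15, -1.1, -0.7, 0.6, 0.2)
  id <- rep(c("a", "b", "c", "d", "e", "f"), each = 2)
  got <- msm_variance_components(r, id)

  # independent oracle: classical one-way ANOVA mean squares with n = 2
  fit <- stats::aov(r ~ factor(id))
  ms <- summary(fit)[[1]]$`Mean Sq`
  msb <- ms[1]; msw <- ms[2]
  expect_equal(got$sigma2_within, msw, tolerance = 1e-10)
  expect_equal(got$sigma2_between, max(0, (msb - msw) / 2), tolerance = 1e-10)
})

test_that("variance decomposition needs at least one repeat subject", {
  expect_error(msm_variance_components(rnorm(5), letters[1:5]), "unidentifiable")
})

test_that("zero within-person variation returns observed intakes unshrunk", {
  subj <- generate_population(15, 15, seed = 50)
  prof <- food_profile("maize_porridge", 1, 300, between_cv = 0.4, within_cv = 0)
  gen <- generate_recalls(subj, profiles = prof,
                          repeat_n_nonpregnant = 10, repeat_n_pregnant = 10, seed = 51)
  di <- compute_daily_intakes(gen$recalls, default_composition(), "folate")
  fit <- fit_usual_intake(di, subj)
  expect_equal(fit$sigma2_within, 0, tolerance = 1e-12)
  expect_true(all(fit$usual_intakes$shrink_factor == 1))
  day1 <- di %>% dplyr::filter(recall_day == 1L)
  m <- match(fit$usual_intakes$subject_id, day1$subject_id)
  expect_equal(fit$usual_intakes$usual_intake, day1$intake[m], tolerance = 1e-6)
})

test_that("shrinkage factors are proper and contract the distribution", {
  subj <- generate_population(80, 80, seed = 60)
  gen <- generate_recalls(subj, repeat_n_nonpregnant = 20, repeat_n_pregnant = 20,
                          seed = 61)
  di <- compute_daily_intakes(gen$recalls, default_composition(), "folate",
                              days = recall_days(gen$recalls, subj))
  fit <- fit_usual_intake(di, subj, shrinkage = "blup")
  u <- fit$usual_intakes
  expect_true(all(u$shrink_factor >= 0 & u$shrink_factor <= 1))
  # two-day subjects are shrunk less than one-day subjects
  expect_gt(min(u$shrink_factor[u$n_days == 2]), max(u$shrink_factor[u$n_days == 1]) - 1e-12)
  # BLUP-shrunk transformed values vary less than unshrunk person means
  d <- di %>%
    dplyr::left_join(subj, by = "subject_id") %>%
    dplyr::mutate(t = boxcox_transform(intake, fit$params)) %>%
    dplyr::group_by(subject_id) %>%
    dplyr::summarise(tbar = mean(t))
  expect_lt(var(u$usual_transformed), var(d$tbar) + 1e-12)
})

test_that("usual intakes are equivariant under rescaling of the data", {
  subj <- generate_population(40, 40, seed = 70)
  gen <- generate_recalls(subj, repeat_n_nonpregnant = 12, repeat_n_pregnant = 12,
                          seed = 71)
  di <- compute_daily_intakes(gen$recalls, default_composition(), "folate",
                              days = recall_days(gen$recalls, subj))
  fit1 <- fit_usual_intake(di, subj)
  k <- 10
  di_k <- di; di_k$intake <- di_k$intake * k
  fit2 <- fit_usual_intake(di_k, subj)
  expect_equal(fit2$usual_intakes$usual_intake,
               fit1$usual_intakes$usual_intake * k, tolerance = 1e-6)
})

test_that("usual-intake fit recovers generator truth at survey scale", {
  subj <- generate_population(164, 159, seed = 80)
  gen <- generate_recalls(subj, seed = 81)
  di <- compute_daily_intakes(gen$recalls, default_composition(), "folate",
                              days = recall_days(gen$recalls, subj))
  fit <- fit_usual_intake(di, subj)
  truth <- gen$truth %>% dplyr::filter(nutrient == "folate")
  expect_lt(
    abs(mean(fit$usual_intakes$usual_intake) - mean(truth$true_usual_intake)) /
      mean(truth$true_usual_intake),
    0.05
  )
  expect_equal(fit$n_repeat, 66)
})

test_that("the Taylor back-transform matches its quadrature oracle", {
  # exact in the degenerate and affine cases
  p0 <- bc(0.5)
  u <- boxcox_transform(c(20, 80, 300), p0)
  expect_equal(back_transform_oracle(u, p0, 0), boxcox_inverse(u, p0))
  p1 <- bc(1)
  u1 <- boxcox_transform(c(20, 80, 300), p1)
  expect_equal(msm_back_transform(u1, p1, 0.5),
               back_transform_oracle(u1, p1, 0.5), tolerance = 1e-8)
  # log case with moderate noise: second-order correction within 2%
  pl <- bc(0)
  ul <- boxcox_transform(c(20, 80, 300), pl)
  t <- msm_back_transform(ul, pl, 0.09)
  o <- back_transform_oracle(ul, pl, 0.09)
  expect_lt(max(abs(t - o) / o), 0.02)
})
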