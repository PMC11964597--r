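# Usual-intake estimation from 1-2 recall days per subject, in the style of
# the Multiple Source Method: day intakes are transformed to approximate
# normality by a two-parameter Box-Cox transformation, regressed on age and
# pregnancy status, the residual variance is decomposed into between- and
# within-person components by the method of moments, person means are shrunk
# toward their covariate prediction, and the shrunken values are
# back-transformed with a second-order bias correction.

#' Two-parameter Box-Cox transformation
#'
#' `T(y) = ((y + s)^lambda - 1) / lambda` for `lambda != 0`, `log(y + s)`
#' for `lambda == 0`. The shift `s` accommodates exact zero intakes
#' (e.g. cobalamin on days without animal-source foods).
#'
#' @param y Numeric vector; `y + shift` must be positive.
#' @param params A `boxcox_params` object, or a list with `lambda` and `shift`.
#' @return Transformed vector.
#' @export
boxcox_transform <- function(y, params) {
  s <- params$shift
  l <- params$lambda
  if (any(y + s <= 0)) stop_validation("y + shift must be positive")
  if (l == 0) log(y + s) else ((y + s)^l - 1) / l
}

#' Inverse Box-Cox transformation
#'
#' Inverse of [boxcox_transform()]. For `lambda != 0` arguments below the
#' branch point (`lambda * z + 1 <= 0`) map to the lower limit `-shift`.
#'
#' @param z Numeric vector on the transformed scale.
#' @param params A `boxcox_params` object.
#' @return Vector on the original scale.
#' @export
boxcox_inverse <- function(z, params) {
  s <- params$shift
  l <- params$lambda
  if (l == 0) exp(z) - s else pmax(l * z + 1, 0)^(1 / l) - s
}

#' Fit a two-parameter Box-Cox transformation
#'
#' Maximizes the Gaussian profile log-likelihood
#' `-n/2 * log(sigma2_mle(T(y))) + (lambda - 1) * sum(log(y + s))` over a
#' lambda grid crossed with a small set of shift candidates. Ties are broken
#' toward the smaller `|lambda|`.
#'
#' @param values Numeric vector, at least 10 values.
#' @param shift_candidates Candidate shifts; defaults to `0` when all values
#'   are positive, otherwise half the smallest positive value and `1.0`.
#' @param lambda_grid Grid of lambda values; default `seq(-2, 2, by = 0.01)`.
#' @return A `boxcox_params` object: list with `lambda`, `shift`, `loglik`.
#' @export
fit_boxcox <- function(values, shift_candidates = NULL,
                       lambda_grid = round(seq(-2, 2, by = 0.01), 2)) {
  values <- as.numeric(values)
  if (length(values) < 10) stop_validation("need at least 10 values to fit Box-Cox")
  if (any(!is.finite(values))) stop_validation("non-finite values")
  if (max(values) == min(values)) {
    stop_validation("all values equal: Box-Cox likelihood is degenerate")
  }
  if (is.null(shift_candidates)) {
    shift_candidates <- if (all(values > 0)) 0 else {
      pos <- values[values > 0]
      if (length(pos) == 0) stop_validation("all values are zero or negative")
      c(min(pos) / 2, 1.0)
    }
  }
  feasible <- shift_candidates[vapply(shift_candidates,
                                      function(s) min(values) + s > 0, logical(1))]
  if (length(feasible) == 0) {
    stop_validation("no shift candidate makes all values positive")
  }
  n <- length(values)
  best <- NULL
  for (s in feasible) {
    ys <- values + s
    logy_sum <- sum(log(ys))
    # n x |grid| matrix of transforms, profile likelihood per column
    tmat <- outer(ys, lambda_grid, function(y, l) {
      ifelse(l == 0, log(y), (y^l - 1) / ifelse(l == 0, NA, l))
    })
    v <- colMeans(tmat^2) - colMeans(tmat)^2
    ll <- -n / 2 * log(v) + (lambda_grid - 1) * logy_sum
    cand <- tibble(lambda = lambda_grid, shift = s, loglik = ll)
    best <- bind_rows(best, cand)
  }
  top <- max(best$loglik)
  ties <- best[best$loglik >= top - 1e-9, ]
  pick <- ties[order(abs(ties$lambda), ties$shift), ][1, ]
  structure(
    list(lambda = pick$lambda, shift = pick$shift, loglik = pick$loglik),
    class = "boxcox_params"
  )
}

#' @export
print.boxcox_params <- function(x, ...) {
  cat(sprintf("<Box-Cox: lambda = %.2f, shift = %g>\n", x$lambda, x$shift))
  invisible(x)
}

#' Between/within-person variance decomposition
#'
#' Method-of-moments decomposition of regression residuals with 1-2
#' observations per subject: the within-person variance is the pooled
#' variance of day residuals around subject means over subjects with two
#' days, `sum_ij (r_ij - rbar_i)^2 / sum_i (n_i - 1)`; the between-person
#' variance is `max(0, var(rbar_i) - sigma2_within * mean_i(1/n_i))`.
#'
#' @param residuals Numeric vector of day-level residuals.
#' @param subject_id Subject identifier per residual.
#' @return List with `sigma2_within`, `sigma2_between`, and `subject_means`
#'   (tibble `subject_id`, `rbar`, `n_days`).
#' @export
msm_variance_components <- function(residuals, subject_id) {
  d <- tibble(r = residuals, subject_id = subject_id) %>%
    group_by(.data$subject_id) %>%
    summarise(rbar = mean(.data$r), n_days = dplyr::n(),
              ss_within = sum((.data$r - mean(.data$r))^2), .groups = "drop")
  denom <- sum(d$n_days - 1)
  if (denom == 0) {
    stop_validation("within-person variance unidentifiable: no subject has a repeat recall")
  }
  sigma2_within <- sum(d$ss_within) / denom
  sigma2_between <- max(0, var(d$rbar) - sigma2_within * mean(1 / d$n_days))
  list(
    sigma2_within = sigma2_within,
    sigma2_between = sigma2_between,
    subject_means = d %>% select("subject_id", "rbar", "n_days")
  )
}

# second derivative of the inverse Box-Cox transform
boxcox_inverse_d2 <- function(z, params) {
  l <- params$lambda
  if (l == 0) exp(z) else (1 - l) * pmax(l * z + 1, 0)^(1 / l - 2)
}

#' Taylor-corrected back-transformation of a usual intake
#'
#' Second-order bias correction for the nonlinearity of the inverse Box-Cox
#' transform: `T^-1(u) + 0.5 * sigma2_within * (T^-1)''(u)`, floored at 0.
#'
#' @param u_transformed Transformed-scale usual intake(s).
#' @param params `boxcox_params`.
#' @param sigma2_within Within-person variance on the transformed scale.
#' @return Usual intake(s) on the original scale.
#' @export
msm_back_transform <- function(u_transformed, params, sigma2_within) {
  pmax(0, boxcox_inverse(u_transformed, params) +
         0.5 * sigma2_within * boxcox_inverse_d2(u_transformed, params))
}

#' Quadrature oracle for the back-transformation
#'
#' Evaluates `E[T^-1(u + e)]` with `e ~ Normal(0, sigma2_within)` by
#' Gauss-Hermite quadrature, for cross-checking the Taylor correction of
#' [msm_back_transform()].
#'
#' @param u_transformed Transformed-scale value(s).
#' @param params `boxcox_params`.
#' @param sigma2_within Normal variance of the perturbation.
#' @param nodes Number of quadrature nodes.
#' @return Expected back-transformed value(s).
#' @export
back_transform_oracle <- function(u_transformed, params, sigma2_within, nodes = 64) {
  if (sigma2_within == 0) return(boxcox_inverse(u_transformed, params))
  gh <- pracma::gaussHermite(nodes)
  vapply(u_transformed, function(u) {
    sum(gh$w * boxcox_inverse(u + sqrt(2 * sigma2_within) * gh$x, params)) / sqrt(pi)
  }, numeric(1))
}

#' Fit the usual-intake model
#'
#' Pipeline: (1) fit a two-parameter Box-Cox transformation to all day-level
#' intakes; (2) OLS of transformed intakes on intercept, age and pregnancy
#' status; (3) method-of-moments variance decomposition of the residuals
#' (see [msm_variance_components()]); (4) per-subject shrinkage of the mean
#' residual: the default multiplies it by `sqrt(c_i)` with
#' `c_i = sigma2_b / (sigma2_b + sigma2_w / n_i)`, which preserves the
#' between-person variance of the predicted values and hence the shape of
#' the usual-intake distribution (the target of the prevalence statistics);
#' the `"blup"` variant multiplies by `c_i`, the best predictor of an
#' individual's intake but one that compresses the distribution's tails;
#' (5) Taylor-corrected back-transformation, floored at 0.
#'
#' All participants are treated as habitual consumers (no episodic
#' two-part model).
#'
#' @param daily_intakes Tibble `subject_id`, `recall_day`, `intake` (and
#'   optionally `nutrient`).
#' @param subjects Subjects tibble supplying the covariates.
#' @param shrinkage `"sqrt"` (default, variance-preserving) or `"blup"`.
#' @return An `msm_fit` object: Box-Cox parameters, regression coefficients,
#'   variance components, per-subject usual intakes, and the repeat count.
#' @export
fit_usual_intake <- function(daily_intakes, subjects, shrinkage = c("sqrt", "blup")) {
  shrinkage <- match.arg(shrinkage)
  validate_subjects(subjects)
  if (any(!is.finite(daily_intakes$intake))) {
    stop_validation("non-finite daily intakes")
  }
  if (any(daily_intakes$intake < 0)) stop_validation("negative daily intakes")
  missing_subj <- setdiff(subjects$subject_id, daily_intakes$subject_id)
  if (length(missing_subj) > 0) {
    stop_validation(sprintf("subject '%s' has no recall day", missing_subj[1]))
  }
  unknown <- setdiff(daily_intakes$subject_id, subjects$subject_id)
  if (length(unknown) > 0) {
    stop_validation(sprintf("daily intakes reference unknown subject '%s'", unknown[1]))
  }
  d <- daily_intakes %>%
    left_join(subjects, by = "subject_id")

  params <- fit_boxcox(d$intake)
  d$t <- boxcox_transform(d$intake, params)

  X <- cbind(1, d$age_y, as.numeric(d$pregnant))
  colnames(X) <- c("(Intercept)", "age_y", "pregnant")
  ols <- stats::lm.fit(X, d$t)
  beta <- ols$coefficients
  d$resid <- ols$residuals

  vc <- msm_variance_components(d$resid, d$subject_id)
  sm <- vc$subject_means %>%
    left_join(subjects, by = "subject_id")
  xb <- beta[1] + beta[2] * sm$age_y + beta[3] * as.numeric(sm$pregnant)
  denom <- vc$sigma2_between + vc$sigma2_within / sm$n_days
  c_i <- ifelse(denom == 0, 1, vc$sigma2_between / denom)
  w <- if (shrinkage == "blup") c_i else sqrt(c_i)
  u_t <- xb + w * sm$rbar
  usual <- msm_back_transform(u_t, params, vc$sigma2_within)

  structure(
    list(
      params = params,
      beta = beta,
      sigma2_within = vc$sigma2_within,
      sigma2_between = vc$sigma2_between,
      shrinkage = shrinkage,
      nutrient = if ("nutrient" %in% names(daily_intakes)) daily_intakes$nutrient[1] else NA_character_,
      usual_intakes = tibble(
        subject_id = sm$subject_id,
        usual_intake = usual,
        n_days = sm$n_days,
        shrink_factor = c_i,
        usual_transformed = u_t
      ),
      n_subjects = nrow(sm),
      n_repeat = sum(sm$n_days >= 2)
    ),
    class = "msm_fit"
  )
}

#' @export
print.msm_fit <- function(x, ...) {
  cat(sprintf(
    paste0("<msm_fit: %d subjects (%d with repeat), lambda = %.2f, shift = %g,\n",
           "          sigma2_within = %.4g, sigma2_between = %.4g, shrinkage = %s>\n"),
    x$n_subjects, x$n_repeat, x$params$lambda, x$params$shift,
    x$sigma2_within, x$sigma2_between, x$shrinkage
  ))
  invisible(x)
}
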