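# multiplicative lognormal noise with unit mean and the requested CV
.lognoise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log1p(cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Simulate a dopamine-depletion imaging study
#'
#' Generates per-subject binding potentials before and after acute DA
#' depletion for a cohort with a common true DA level: baseline
#' `BP = B_max/(1 + Y)`, depleted `BP = B_max/(1 + alpha*Y)`, each multiplied
#' by independent multiplicative lognormal measurement noise with unit mean
#' and coefficient of variation `noise_cv` (imaging noise scales with
#' signal, and BP is positive).
#'
#' @param true_y true normalized DA concentration (>= 0).
#' @param b_max relative receptor density (> 0).
#' @param alpha residual DA fraction after depletion, in \[0, 1).
#' @param n_subjects number of subjects (>= 1).
#' @param noise_cv coefficient of variation of the measurement noise (>= 0).
#' @param seed optional integer seed; the same seed reproduces the same
#'   study exactly.
#' @return A list of [depletion_observation()] objects.
#' @examples
#' obs <- generate_depletion_study(0.266, n_subjects = 3, noise_cv = 0.05,
#'                                 seed = 1)
#' sapply(obs, estimate_da_from_depletion)
#' @export
generate_depletion_study <- function(true_y, b_max = 1, alpha = 0.3,
                                     n_subjects = 1, noise_cv = 0,
                                     seed = NULL) {
  stopifnot(is.numeric(true_y), true_y >= 0, b_max > 0,
            alpha >= 0, alpha < 1, n_subjects >= 1, noise_cv >= 0)
  if (!is.null(seed)) set.seed(seed)
  bp0 <- b_max / (1 + true_y) * .lognoise(n_subjects, noise_cv)
  bp1 <- b_max / (1 + alpha * true_y) * .lognoise(n_subjects, noise_cv)
  lapply(seq_len(n_subjects), function(i)
    depletion_observation(bp0[i], bp1[i], alpha))
}

#' Estimate the baseline DA level from one depletion observation
#'
#' Computes the fractional BP increase of a [depletion_observation()] and
#' inverts it via [estimate_da_from_bp_increase()].  Noisy observations can
#' show a BP decrease; these are censored at `beta = 0` (estimate `Y = 0`),
#' the boundary of the physical domain.
#'
#' @param obs a [depletion_observation()].
#' @return Estimated normalized DA concentration (>= 0).
#' @export
estimate_da_from_depletion <- function(obs) {
  stopifnot(inherits(obs, "depletion_observation"))
  beta <- max(0, obs$bp_depleted / obs$bp_baseline - 1)
  estimate_da_from_bp_increase(beta, obs$alpha)
}

#' Simulate patient outcome records for the symptom-change regression
#'
#' Generates `(beta, delta_panss_pos)` pairs: each subject's fractional BP
#' increase `beta` is mapped to a PFC activity via [pfc_activity_from_beta()]
#' and the change in the PANSS positive subscale is drawn from the line
#' `slope * x_p + intercept` plus Gaussian residual noise.  With `sigma = 0`
#' the records lie exactly on the line, so the regression must recover the
#' generating coefficients to machine precision.
#'
#' @param n number of subjects.
#' @param beta fractional BP increases; default evenly spaced over
#'   \[0.02, 0.45\] (the feasible depletion-response range at `alpha = 0.3`).
#' @param slope,intercept generating line for `delta_panss_pos` vs `x_p`.
#' @param sigma residual standard deviation (score points).
#' @param alpha residual DA fraction used in the transformation.
#' @param a,b D2 coefficients of the transformation (default 0, 0).
#' @param seed optional integer seed.
#' @return A data frame with columns `beta`, `delta_panss_pos`.
#' @export
generate_outcome_records <- function(n = 14, beta = NULL,
                                     slope = 49.6, intercept = -61.5,
                                     sigma = 0, alpha = 0.3, a = 0, b = 0,
                                     seed = NULL) {
  stopifnot(n >= 1, sigma >= 0)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(beta)) beta <- seq(0.02, 0.45, length.out = n)
  stopifnot(length(beta) == n, all(beta >= 0))
  x_p <- pfc_activity_from_beta(beta, alpha = alpha, a = a, b = b)
  delta <- slope * x_p + intercept + stats::rnorm(n, 0, sigma)
  data.frame(beta = beta, delta_panss_pos = delta)
}
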