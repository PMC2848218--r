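#' Optimum antipsychotic regimen under the net-binding criterion
#'
#' Solves for the normalized antipsychotic concentration `F/K_APD` at which
#' the receptor-density-weighted occupancy by endogenous DA in patients is
#' reduced to the healthy-control level:
#' \deqn{B_{max,SZ} \, P_{DA(APD),SZ} = B_{max,HC} \, P_{DA,HC}.}
#' Under competitive binding the residual DA occupancy is
#' \eqn{Y_{SZ}/(1 + Y_{SZ} + F/K_{APD})}, giving the closed form
#' \deqn{F/K_{APD} = Y_{SZ}\,B_{max,SZ}/(B_{max,HC} P_{DA,HC}) - (1 + Y_{SZ}).}
#' A negative solution means the patient's net binding is already at or
#' below the control level and no drug is needed; strictly negative targets
#' raise an infeasibility error, an exact zero returns a drug-free regimen.
#'
#' @param model a [build_model()] calibration.
#' @return An object of class `drug_regimen`: a list with `f_over_k`,
#'   `p_da_apd` (residual DA occupancy), `p_apd` (drug occupancy),
#'   `p_total`, `p_free`, and the `target` net binding per patient receptor.
#' @examples
#' optimum_regimen(build_model(0.12, 0.21, 1.2, "Model 1"))
#' @export
optimum_regimen <- function(model) {
  stopifnot(inherits(model, "calibrated_model"))
  p_hc <- occupancy_from_da(model$hc$y)
  y_sz <- model$sz$y
  target <- model$hc$b_max * p_hc / model$sz$b_max
  if (target <= 0) {  # control occupancy zero: criterion needs no drug
    f <- if (y_sz > 0)
      stop("infeasible: control net binding is zero but the patient's is not",
           call. = FALSE) else 0
  } else {
    f <- y_sz / target - (1 + y_sz)
  }
  if (f < -1e-12)
    stop("infeasible: patient net binding is already at or below the ",
         "control level; the criterion would require a negative drug ",
         "concentration", call. = FALSE)
  f <- max(f, 0)
  occ <- occupancies_with_drug(y_sz, f)
  structure(list(f_over_k = f,
                 p_da_apd = occ$p_da_apd,
                 p_apd = occ$p_apd,
                 p_total = occ$p_da_apd + occ$p_apd,
                 p_free = occ$p_free,
                 target = target,
                 model_label = model$label),
            class = "drug_regimen")
}

#' @export
print.drug_regimen <- function(x, ...) {
  cat(sprintf("Optimum antipsychotic regimen%s\n",
              if (nzchar(x$model_label)) paste0(" (", x$model_label, ")")
              else ""))
  cat(sprintf("  F/K_APD (normalized concentration): %.2f\n", x$f_over_k))
  cat(sprintf("  drug occupancy P_APD              : %.1f%%\n",
              100 * x$p_apd))
  cat(sprintf("  residual DA occupancy P_DA(APD)   : %.1f%%\n",
              100 * x$p_da_apd))
  cat(sprintf("  total D2 occupancy                : %.1f%%\n",
              100 * x$p_total))
  invisible(x)
}

#' PFC activity implied by a depletion-induced BP increase
#'
#' Chains the depletion inversion with the equilibrium inversion: the
#' fractional BP increase `beta` gives the normalized DA level
#' `Y = beta/(1 - alpha(1+beta))`, whose occupancy `P = Y/(1+Y)` yields the
#' PFC activity
#' \deqn{X_p = (J_d - Y/(1 - aP)) / (1 - bP).}
#' At `(a, b) = (0, 0)` this reduces to `X_p = J_d - Y`, strictly decreasing
#' in `beta`.
#'
#' @param beta fractional BP increase after depletion (>= 0); vectorized.
#' @param alpha residual DA fraction, default 0.3.
#' @param a,b D2 auto-/heteroreceptor coefficients.
#' @param j_d tonic drive.
#' @param b_max relative receptor density; with
#'   `scale_with_density = TRUE` the D2 coefficients are scaled to
#'   `a * b_max`, `b * b_max` (irrelevant at `(a, b) = (0, 0)`).
#' @param scale_with_density logical, default `FALSE`.
#' @return PFC activity `x_p` (> 0); errors if any point is infeasible.
#' @examples
#' pfc_activity_from_beta(0.1724)  # ~0.734
#' @export
pfc_activity_from_beta <- function(beta, alpha = 0.3, a = 0, b = 0,
                                   j_d = 1, b_max = 1,
                                   scale_with_density = FALSE) {
  y <- estimate_da_from_bp_increase(beta, alpha)
  eff <- .effective_ab(a, b, b_max, scale_with_density)
  vapply(y, function(yi)
    .invert_equilibrium(yi, eff$a, eff$b, j_d)$x_p, numeric(1))
}

#' Regress symptom change on model-derived PFC activity
#'
#' Transforms each patient's depletion response `beta` into a PFC activity
#' via [pfc_activity_from_beta()] and fits the ordinary least-squares
#' regression of the PANSS positive-subscale change on that activity
#' (negative change = improvement).  The slope test is the standard
#' two-sided t-test.
#'
#' @param records data frame with columns `beta` and `delta_panss_pos`
#'   (at least 3 rows).
#' @param alpha residual DA fraction used in the transformation.
#' @param a,b D2 coefficients of the transformation (default `(0, 0)`).
#' @param ... passed on to [pfc_activity_from_beta()] (e.g. `b_max`,
#'   `scale_with_density`).
#' @return An object of class `outcome_fit` with the fitted [stats::lm]
#'   model, the transformed data, and the headline numbers `slope`,
#'   `intercept`, `r_squared`, `p_value`, `n`.
#' @examples
#' rec <- generate_outcome_records(n = 8)
#' fit_outcome_regression(rec)
#' @export
fit_outcome_regression <- function(records, alpha = 0.3, a = 0, b = 0, ...) {
  stopifnot(is.data.frame(records),
            all(c("beta", "delta_panss_pos") %in% names(records)))
  if (nrow(records) < 3L)
    stop("at least 3 patient records are required", call. = FALSE)
  x_p <- pfc_activity_from_beta(records$beta, alpha = alpha, a = a, b = b,
                                ...)
  if (stats::sd(x_p) == 0)
    stop("degenerate records: transformed PFC activity is constant",
         call. = FALSE)
  d <- data.frame(x_p = x_p, delta_panss_pos = records$delta_panss_pos,
                  beta = records$beta)
  fit <- stats::lm(delta_panss_pos ~ x_p, data = d)
  sm <- summary(fit)
  structure(list(fit = fit, data = d,
                 slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 r_squared = sm$r.squared,
                 p_value = sm$coefficients["x_p", "Pr(>|t|)"],
                 n = nrow(d), alpha = alpha, a = a, b = b),
            class = "outcome_fit")
}

#' @export
print.outcome_fit <- function(x, ...) {
  cat("Symptom-change regression on model-derived PFC activity\n")
  cat(sprintf("  n = %d, alpha = %.2f, (a, b) = (%.2g, %.2g)\n",
              x$n, x$alpha, x$a, x$b))
  cat(sprintf("  dPANSSp = %.1f * X_p %+.1f   (R^2 = %.2f, p = %.3g)\n",
              x$slope, x$intercept, x$r_squared, x$p_value))
  invisible(x)
}

#' @export
summary.outcome_fit <- function(object, ...) summary(object$fit, ...)

#' @export
coef.outcome_fit <- function(object, ...) stats::coef(object$fit, ...)

#' @export
residuals.outcome_fit <- function(object, ...) stats::residuals(object$fit, ...)

#' @export
predict.outcome_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(stats::predict(object$fit, ...))
  if (!("x_p" %in% names(newdata)) && "beta" %in% names(newdata))
    newdata$x_p <- pfc_activity_from_beta(newdata$beta, alpha = object$alpha,
                                          a = object$a, b = object$b)
  stats::predict(object$fit, newdata = newdata, ...)
}

#' @export
plot.outcome_fit <- function(x, ...) {
  graphics::plot(x$data$x_p, x$data$delta_panss_pos,
                 xlab = "PFC activity X_p",
                 ylab = "change in PANSS positive subscale", ...)
  graphics::abline(x$fit, lty = 2)
  invisible(x)
}
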