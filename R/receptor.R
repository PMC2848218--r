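#' Receptor system for one cohort
#'
#' Bundles the two quantities that determine striatal D2 availability in one
#' cohort: the relative receptor density \eqn{B_{max}} (healthy-control
#' reference = 1) and the normalized extracellular dopamine concentration
#' \eqn{Y = [DA]/K_{DA}}.  All binding computations in the package work on
#' these dimensionless ratios; absolute concentrations and dissociation
#' constants never enter.
#'
#' @param b_max relative D2 receptor density (> 0; HC reference is 1).
#' @param y normalized extracellular DA concentration \eqn{[DA]/K_{DA}}
#'   (>= 0).
#' @param cohort free-text cohort label, e.g. `"HC"` or `"SZ"`.
#' @return An object of class `receptor_system`.
#' @examples
#' hc <- receptor_system(1.0, 0.136, "HC")
#' binding_potential(hc)
#' @export
receptor_system <- function(b_max, y, cohort = "") {
  stopifnot(is.numeric(b_max), length(b_max) == 1L, is.finite(b_max),
            is.numeric(y), length(y) == 1L, is.finite(y))
  if (b_max <= 0) stop("'b_max' must be strictly positive", call. = FALSE)
  if (y < 0) stop("'y' must be non-negative", call. = FALSE)
  structure(list(b_max = b_max, y = y, cohort = as.character(cohort)),
            class = "receptor_system")
}

#' @export
print.receptor_system <- function(x, ...) {
  cat(sprintf("Receptor system%s\n",
              if (nzchar(x$cohort)) paste0(" [", x$cohort, "]") else ""))
  cat(sprintf("  B_max (relative density): %.4g\n", x$b_max))
  cat(sprintf("  Y = [DA]/K_DA           : %.4g\n", x$y))
  cat(sprintf("  D2 occupancy by DA      : %.1f%%\n",
              100 * occupancy_from_da(x$y)))
  invisible(x)
}

#' One subject of a dopamine-depletion imaging study
#'
#' Records a D2 binding potential measured before and after acute dopamine
#' depletion (e.g. by AMPT), together with the residual DA fraction `alpha`
#' assumed to remain after depletion.  Depletion unmasks receptors, so the
#' post-depletion BP is at least the baseline BP whenever endogenous DA is
#' present.
#'
#' @param bp_baseline binding potential before depletion (> 0, arbitrary
#'   units).
#' @param bp_depleted binding potential after depletion (> 0, same units).
#' @param alpha residual DA fraction after depletion, in \[0, 1); the default
#'   0.3 corresponds to 70% depletion.
#' @return An object of class `depletion_observation`.
#' @seealso [estimate_da_from_bp_increase()] for turning the fractional BP
#'   increase into a normalized DA level.
#' @export
depletion_observation <- function(bp_baseline, bp_depleted, alpha = 0.3) {
  stopifnot(is.numeric(bp_baseline), is.numeric(bp_depleted),
            is.numeric(alpha))
  if (bp_baseline <= 0 || bp_depleted <= 0)
    stop("binding potentials must be strictly positive", call. = FALSE)
  if (alpha < 0 || alpha >= 1)
    stop("'alpha' must lie in [0, 1)", call. = FALSE)
  structure(list(bp_baseline = bp_baseline, bp_depleted = bp_depleted,
                 alpha = alpha),
            class = "depletion_observation")
}

#' Relative D2 binding potential
#'
#' Single-site binding: BP is proportional to receptor density times the
#' fraction of receptors not occupied by endogenous DA,
#' \deqn{BP \propto B_{max} / (1 + Y),}
#' with \eqn{Y = [DA]/K_{DA}}.  Only ratios of BP values are meaningful, so
#' the proportionality constant is fixed at 1.
#'
#' @param system a [receptor_system()].
#' @return Relative binding potential (dimensionless).
#' @export
binding_potential <- function(system) {
  if (!inherits(system, "receptor_system"))
    system <- receptor_system(system$b_max, system$y,
                              if (is.null(system$cohort)) "" else system$cohort)
  system$b_max / (1 + system$y)
}

#' D2 receptor occupancy by endogenous dopamine
#'
#' Saturation binding at a single site: \eqn{P = Y/(1+Y)} with
#' \eqn{Y = [DA]/K_{DA}}.  Strictly increasing in `y`, bounded below 1.
#'
#' @param y normalized DA concentration (>= 0); vectorized.
#' @return Occupancy fraction in \[0, 1).
#' @examples
#' occupancy_from_da(0.136)  # ~0.12
#' @export
occupancy_from_da <- function(y) {
  stopifnot(is.numeric(y))
  if (any(!is.finite(y)) || any(y < 0))
    stop("'y' must be finite and non-negative", call. = FALSE)
  y / (1 + y)
}

#' Normalized DA concentration from occupancy
#'
#' Algebraic inverse of [occupancy_from_da()]: \eqn{Y = P/(1-P)}.
#'
#' @param p occupancy fraction in \[0, 1); vectorized.
#' @return Normalized DA concentration \eqn{Y}.
#' @examples
#' da_from_occupancy(0.21)  # ~0.266
#' @export
da_from_occupancy <- function(p) {
  stopifnot(is.numeric(p))
  if (any(!is.finite(p)) || any(p < 0) || any(p >= 1))
    stop("'p' must lie in [0, 1)", call. = FALSE)
  p / (1 - p)
}

#' BP ratio after vs before dopamine depletion
#'
#' With receptor density unchanged by acute depletion and a residual DA
#' fraction `alpha`, the post/pre binding-potential ratio is
#' \deqn{BP_{depleted}/BP_{baseline} = (1 + Y)/(1 + \alpha Y) \ge 1.}
#'
#' @param y normalized DA concentration before depletion (>= 0).
#' @param alpha residual DA fraction in \[0, 1); default 0.3 (70% depletion).
#' @return The ratio (>= 1; equal to 1 only when `y = 0`).
#' @export
bp_depletion_ratio <- function(y, alpha = 0.3) {
  stopifnot(is.numeric(y), is.numeric(alpha))
  if (any(y < 0)) stop("'y' must be non-negative", call. = FALSE)
  if (any(alpha < 0) || any(alpha >= 1))
    stop("'alpha' must lie in [0, 1)", call. = FALSE)
  (1 + y) / (1 + alpha * y)
}

#' Estimate the baseline DA level from a depletion-induced BP increase
#'
#' Inverts [bp_depletion_ratio()] at a known residual fraction: writing
#' `beta` for the fractional BP increase
#' \eqn{\beta = (BP_{depleted} - BP_{baseline})/BP_{baseline}},
#' \deqn{Y = \beta / (1 - \alpha (1 + \beta)).}
#' The observation is infeasible when \eqn{\alpha(1+\beta) \ge 1}: no finite
#' DA level can produce that large a BP increase with that little depletion.
#'
#' @param beta fractional BP increase (>= 0); vectorized.
#' @param alpha residual DA fraction in \[0, 1); default 0.3.
#' @return Normalized DA concentration \eqn{Y} (>= 0).
#' @examples
#' estimate_da_from_bp_increase(bp_depletion_ratio(0.266, 0.3) - 1, 0.3)
#' @export
estimate_da_from_bp_increase <- function(beta, alpha = 0.3) {
  stopifnot(is.numeric(beta), is.numeric(alpha))
  if (any(beta < 0)) stop("'beta' must be non-negative", call. = FALSE)
  if (any(alpha < 0) || any(alpha >= 1))
    stop("'alpha' must lie in [0, 1)", call. = FALSE)
  denom <- 1 - alpha * (1 + beta)
  if (any(denom <= 0))
    stop("infeasible observation: alpha * (1 + beta) >= 1 ",
         "(BP increase too large for the assumed depletion)", call. = FALSE)
  beta / denom
}

#' D2 occupancies under competition between DA and an antipsychotic drug
#'
#' Two ligands competing for one site; with the drug concentration expressed
#' as the ratio to its dissociation constant, \eqn{F/K_{APD}},
#' \deqn{P_{DA(APD)} = Y / (1 + Y + F/K_{APD}), \quad
#'       P_{APD} = (F/K_{APD}) / (1 + Y + F/K_{APD}).}
#' The unoccupied fraction \eqn{1/(1+Y+F/K_{APD})} completes the partition.
#'
#' @param y normalized DA concentration (>= 0).
#' @param f_over_k normalized free drug concentration \eqn{F/K_{APD}} (>= 0).
#' @return A list with components `p_da_apd` (residual DA occupancy),
#'   `p_apd` (drug occupancy) and `p_free` (unoccupied fraction); the three
#'   sum to 1 exactly.
#' @examples
#' occupancies_with_drug(0.266, 1.39)
#' @export
occupancies_with_drug <- function(y, f_over_k) {
  stopifnot(is.numeric(y), is.numeric(f_over_k))
  if (any(y < 0)) stop("'y' must be non-negative", call. = FALSE)
  if (any(f_over_k < 0)) stop("'f_over_k' must be non-negative", call. = FALSE)
  denom <- 1 + y + f_over_k
  list(p_da_apd = y / denom, p_apd = f_over_k / denom, p_free = 1 / denom)
}

#' Patient-to-control binding-potential ratio
#'
#' \deqn{BP_{SZ}/BP_{HC} = (B_{max,SZ}/B_{max,HC}) (1 + Y_{HC})/(1 + Y_{SZ}),}
#' assuming a common tracer dissociation constant across cohorts.  Identical
#' to the ratio of the two [binding_potential()] values.
#'
#' @param sz,hc [receptor_system()] objects for patients and controls.
#' @return The BP ratio (dimensionless).
#' @export
bp_ratio_sz_hc <- function(sz, hc) {
  binding_potential(sz) / binding_potential(hc)
}
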