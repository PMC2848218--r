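#' Read a table of published D2 occupancy estimates
#'
#' Reads a long-format CSV of striatal D2 receptor occupancies by endogenous
#' DA, one row per study-cohort combination with an available estimate
#' (columns `study_label`, `cohort`, `occupancy_percent`).  Absent cells of
#' the source table simply have no row; they are never coded as zero.  The
#' packaged fixture collects the dopamine-depletion imaging estimates used to
#' calibrate the two canonical models.
#'
#' @param path CSV path; defaults to the packaged study table.
#' @return A data frame with columns `study_label`, `cohort` (`"HC"` or
#'   `"SZ"`), and `occupancy` (fraction in \[0, 1)).
#' @examples
#' head(read_occupancy_table())
#' @export
read_occupancy_table <- function(path = system.file("extdata",
                                                    "d2_occupancy_studies.csv",
                                                    package = "frontostriatal")) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("study_label", "cohort", "occupancy_percent")
  if (!all(need %in% names(tab)))
    stop("occupancy table must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  for (i in seq_len(nrow(tab))) {
    if (!tab$cohort[i] %in% c("HC", "SZ"))
      stop(sprintf("row %d (%s): cohort must be 'HC' or 'SZ'",
                   i, tab$study_label[i]), call. = FALSE)
    oc <- tab$occupancy_percent[i]
    if (!is.finite(oc) || oc < 0 || oc >= 100)
      stop(sprintf("row %d (%s): occupancy_percent must lie in [0, 100)",
                   i, tab$study_label[i]), call. = FALSE)
  }
  data.frame(study_label = tab$study_label, cohort = tab$cohort,
             occupancy = tab$occupancy_percent / 100,
             stringsAsFactors = FALSE)
}

#' Average healthy-control D2 occupancy across studies
#'
#' Unweighted arithmetic mean of the healthy-control occupancies; patient
#' rows are ignored.
#'
#' @param records data frame as returned by [read_occupancy_table()].
#' @return Mean HC occupancy (fraction).
#' @export
average_hc_occupancy <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("cohort", "occupancy") %in% names(records)))
  occ <- records$occupancy[records$cohort == "HC" & !is.na(records$occupancy)]
  if (!length(occ))
    stop("no healthy-control occupancy records available", call. = FALSE)
  mean(occ)
}

#' Extrapolate a patient occupancy from a control occupancy
#'
#' Scales a healthy-control occupancy by the patient:control occupancy ratio
#' of a reference calibrated model (e.g. 21%/12% from the single study with
#' both cohorts).
#'
#' @param hc_occupancy control occupancy (fraction).
#' @param ratio_model a [build_model()] result supplying the SZ/HC occupancy
#'   ratio.
#' @return Extrapolated patient occupancy (fraction).
#' @export
extrapolate_sz_occupancy <- function(hc_occupancy, ratio_model) {
  stopifnot(inherits(ratio_model, "calibrated_model"))
  p_hc <- occupancy_from_da(ratio_model$hc$y)
  p_sz <- occupancy_from_da(ratio_model$sz$y)
  if (p_hc <= 0)
    stop("reference model has zero control occupancy; ratio undefined",
         call. = FALSE)
  hc_occupancy * p_sz / p_hc
}

#' Build a patient/control receptor calibration
#'
#' Constructs the paired [receptor_system()]s of a calibrated model from the
#' two cohort occupancies and the relative patient receptor density.  The
#' control density is normalized to 1; the normalized DA levels are
#' `Y = P/(1-P)` per cohort.
#'
#' @param p_hc,p_sz D2 occupancy by DA in controls and patients (fractions
#'   in \[0, 1)).
#' @param b_max_sz relative patient receptor density (control = 1).
#' @param label model label, e.g. `"Model 1"`.
#' @return An object of class `calibrated_model` with elements `label`,
#'   `hc`, `sz`.
#' @examples
#' build_model(0.12, 0.21, b_max_sz = 1.2, label = "Model 1")
#' @export
build_model <- function(p_hc, p_sz, b_max_sz = 1.2, label = "") {
  structure(list(label = label,
                 hc = receptor_system(1, da_from_occupancy(p_hc), "HC"),
                 sz = receptor_system(b_max_sz, da_from_occupancy(p_sz), "SZ")),
            class = "calibrated_model")
}

#' @export
print.calibrated_model <- function(x, ...) {
  cat(sprintf("Calibrated receptor model%s\n",
              if (nzchar(x$label)) paste0(": ", x$label) else ""))
  for (cohort in c("hc", "sz")) {
    s <- x[[cohort]]
    cat(sprintf("  %s: B_max = %.3g, P = %.1f%%, Y = %.3f\n",
                toupper(cohort), s$b_max, 100 * occupancy_from_da(s$y), s$y))
  }
  invisible(x)
}

#' @export
summary.calibrated_model <- function(object, ...) {
  d <- data.frame(cohort = c("HC", "SZ"),
                  b_max = c(object$hc$b_max, object$sz$b_max),
                  occupancy = occupancy_from_da(c(object$hc$y, object$sz$y)),
                  y = c(object$hc$y, object$sz$y))
  cat(sprintf("Calibrated receptor model%s\n\n",
              if (nzchar(object$label)) paste0(": ", object$label) else ""))
  print(d, row.names = FALSE, digits = 4)
  invisible(d)
}

#' The two canonical patient/control calibrations
#'
#' Model 1 takes both cohort occupancies (12% and 21%) from the single
#' depletion study that imaged both groups.  Model 2 averages the control
#' occupancies across all available studies (23.6%), extrapolates the
#' patient occupancy with Model 1's patient:control ratio (41.3%), and
#' rounds both to whole percent (24% and 41%).  Both models use a relative
#' patient receptor density of 1.2.
#'
#' @param records occupancy table (see [read_occupancy_table()]); defaults
#'   to the packaged study table.
#' @param b_max_sz relative patient receptor density.
#' @return A list with elements `model1` and `model2` (class
#'   `calibrated_model`) plus `hc_average` and `sz_extrapolated`
#'   (unrounded fractions).
#' @export
canonical_models <- function(records = read_occupancy_table(),
                             b_max_sz = 1.2) {
  both <- records[records$study_label %in%
                    records$study_label[records$cohort == "HC"] &
                  records$study_label %in%
                    records$study_label[records$cohort == "SZ"], ]
  if (!nrow(both))
    stop("no study reports both cohorts; cannot build Model 1", call. = FALSE)
  ref <- both$study_label[1L]
  p_hc1 <- both$occupancy[both$study_label == ref & both$cohort == "HC"][1L]
  p_sz1 <- both$occupancy[both$study_label == ref & both$cohort == "SZ"][1L]
  model1 <- build_model(p_hc1, p_sz1, b_max_sz, label = "Model 1")

  hc_avg <- average_hc_occupancy(records)
  sz_ext <- extrapolate_sz_occupancy(hc_avg, model1)
  model2 <- build_model(round(hc_avg, 2), round(sz_ext, 2), b_max_sz,
                        label = "Model 2")
  list(model1 = model1, model2 = model2,
       hc_average = hc_avg, sz_extrapolated = sz_ext)
}

# cohort-effective D2 coefficients: receptor effects scale with relative
# density in cross-cohort comparisons (a patient with 1.2x the receptors
# feels 1.2x the presynaptic modulation)
.effective_ab <- function(a, b, b_max, scale_with_density) {
  if (scale_with_density) list(a = a * b_max, b = b * b_max)
  else list(a = a, b = b)
}

# invert the equilibrium at a known DA level: given Y (hence P), recover the
# frontostriatal efficacy factor and the PFC activity
.invert_equilibrium <- function(y, a_eff, b_eff, j_d) {
  p <- occupancy_from_da(y)
  ga <- 1 - a_eff * p
  gb <- 1 - b_eff * p
  if (ga <= 0 || gb <= 0)
    stop("infeasible: effective D2 modulation reaches total suppression ",
         "(a*P or b*P >= 1)", call. = FALSE)
  x_p <- (j_d - y / ga) / gb
  if (x_p <= 0)
    stop("infeasible: implied PFC activity is not positive", call. = FALSE)
  list(v_ps = gb, x_p = x_p, p = p)
}

#' Glutamatergic efficacy and PFC activity implied by a calibration
#'
#' Inverts the circuit equilibrium at each cohort's calibrated DA level: the
#' normalized frontostriatal synaptic efficacy is the heteroreceptor factor
#' `V_ps = 1 - b_eff * P`, and the PFC activity is
#' `X_p = (J_d - Y/(1 - a_eff * P)) / (1 - b_eff * P)`.  By default the D2
#' coefficients scale with the cohort's relative receptor density
#' (`a_eff = a * B_max`, `b_eff = b * B_max`), so patients with denser D2
#' receptors feel proportionally stronger presynaptic modulation.
#'
#' @param model a [build_model()] result.
#' @param a,b D2 auto-/heteroreceptor coefficients (control-referenced).
#' @param j_d tonic drive to the DA nuclei.
#' @param scale_with_density logical; scale `a`, `b` by each cohort's
#'   `b_max`.
#' @return A data frame with one row per cohort: `cohort`, `v_ps`, `x_p`,
#'   `y`, `p`.
#' @examples
#' m1 <- build_model(0.12, 0.21, 1.2, "Model 1")
#' efficacy_and_pfc(m1, a = 0, b = 0)  # x_p = 1 - Y per cohort
#' @export
efficacy_and_pfc <- function(model, a = 0, b = 0, j_d = 1,
                             scale_with_density = TRUE) {
  stopifnot(inherits(model, "calibrated_model"), a >= 0, b >= 0, j_d > 0)
  rows <- lapply(c("hc", "sz"), function(cohort) {
    s <- model[[cohort]]
    eff <- .effective_ab(a, b, s$b_max, scale_with_density)
    inv <- .invert_equilibrium(s$y, eff$a, eff$b, j_d)
    data.frame(cohort = toupper(cohort), v_ps = inv$v_ps, x_p = inv$x_p,
               y = s$y, p = inv$p)
  })
  do.call(rbind, rows)
}

#' Patient-minus-control differences in efficacy and PFC activity
#'
#' Sweeps the heteroreceptor coefficient `b` (for each autoreceptor
#' coefficient `a`) and returns the SZ-minus-HC differences in the
#' normalized glutamatergic efficacy and the PFC activity.  The efficacy
#' difference does not involve `a`, so its curve is identical across `a`
#' values; the PFC-activity difference does depend on `a`.  Grid points
#' where either cohort's inversion is infeasible are flagged rather than
#' dropped.
#'
#' @param model a [build_model()] result.
#' @param a numeric vector of autoreceptor coefficients.
#' @param b numeric vector of heteroreceptor coefficients.
#' @param j_d tonic drive.
#' @param scale_with_density see [efficacy_and_pfc()].
#' @return A data frame with columns `a`, `b`, `d_v_ps`, `d_x_p`,
#'   `feasible`.
#' @export
sz_hc_differences <- function(model, a = 0, b = seq(0, 1, by = 0.05),
                              j_d = 1, scale_with_density = TRUE) {
  stopifnot(inherits(model, "calibrated_model"))
  grid <- expand.grid(a = a, b = b, KEEP.OUT.ATTRS = FALSE)
  out <- data.frame(grid, d_v_ps = NA_real_, d_x_p = NA_real_,
                    feasible = FALSE)
  for (i in seq_len(nrow(grid))) {
    res <- tryCatch(
      efficacy_and_pfc(model, a = grid$a[i], b = grid$b[i], j_d = j_d,
                       scale_with_density = scale_with_density),
      error = function(e) NULL)
    if (!is.null(res)) {
      out$d_v_ps[i] <- res$v_ps[res$cohort == "SZ"] -
        res$v_ps[res$cohort == "HC"]
      out$d_x_p[i] <- res$x_p[res$cohort == "SZ"] -
        res$x_p[res$cohort == "HC"]
      out$feasible[i] <- TRUE
    }
  }
  out
}
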