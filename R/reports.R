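# formatting conventions for reports: occupancies to one decimal percent,
# normalized DA levels to three decimals
.fmt_pct <- function(x) sprintf("%.1f%%", 100 * x)
.fmt_y <- function(x) sprintf("%.3f", x)

#' Equilibrium-sweep report
#'
#' Computes the striatal-activity and DA-release curves over a grid of PFC
#' activities and D2 coefficients, writes them as a tidy CSV (columns `x_p`,
#' `a`, `b`, `j_d`, `x_s`, `x_d`, `y`, `p`, `feasible`), and prints the
#' three-column reference block at `x_p = 0.7`: no D2 effects, the
#' heteroreceptor alone (`b = 1`), and hetero- plus autoreceptor
#' (`a = 0.2, b = 1`).  Output is deterministic: repeated runs with the same
#' configuration are byte-identical.
#'
#' @param out_csv optional path for the sweep CSV.
#' @param x_p,a,b,j_d sweep grids, defaulting to the reference
#'   configuration: `x_p` in \[0.05, 0.95\], `b` in `{0, 0.25, 0.5, 0.75, 1}`,
#'   `a` in `{0, 0.2}`.
#' @param quiet suppress printing.
#' @return Invisibly, a list with the full `sweep` data frame and the
#'   `reference` block at `x_p = 0.7`.
#' @export
run_equilibrium_sweep <- function(out_csv = NULL,
                                  x_p = seq(0.05, 0.95, by = 0.01),
                                  a = c(0, 0.2),
                                  b = c(0, 0.25, 0.5, 0.75, 1),
                                  j_d = 1, quiet = FALSE) {
  if (!length(x_p) || !length(a) || !length(b))
    stop("empty sweep grid", call. = FALSE)
  sweep <- sweep_equilibrium(x_p = x_p, a = a, b = b, j_d = j_d)
  if (!is.null(out_csv))
    utils::write.csv(sweep, out_csv, row.names = FALSE)

  ref_cases <- data.frame(a = c(0, 0, 0.2), b = c(0, 1, 1))
  ref <- do.call(rbind, lapply(seq_len(nrow(ref_cases)), function(i) {
    eq <- solve_equilibrium(circuit_params(a = ref_cases$a[i],
                                           b = ref_cases$b[i], j_d = j_d),
                            x_p = 0.7)
    data.frame(a = ref_cases$a[i], b = ref_cases$b[i],
               x_s = eq$x_s, y = eq$y)
  }))
  if (!quiet) {
    cat("Striatal activity and DA release at X_p = 0.7:\n")
    cat(sprintf("  (a, b) = (%.1f, %.2f): X_s = %.2f, Y = %.2f\n",
                ref$a, ref$b, ref$x_s, ref$y), sep = "")
    enh <- enhancement_percent(ref$y[-1L], ref$y[1L])
    cat(sprintf("  DA-release enhancement vs no D2 effects: %+.0f%% (b = 1), %+.0f%% (a = 0.2, b = 1)\n",
                enh[1L], enh[2L]))
    if (!is.null(out_csv)) cat(sprintf("  sweep written to %s\n", out_csv))
  }
  invisible(list(sweep = sweep, reference = ref))
}

#' Calibration report
#'
#' Reads a D2 occupancy study table, builds the two canonical
#' patient/control models, prints the calibration summary (densities,
#' occupancies, normalized DA levels), and computes the SZ-minus-HC
#' difference curves of glutamatergic efficacy and PFC activity over the
#' heteroreceptor coefficient.
#'
#' @param fixture path to the occupancy CSV; default the packaged table.
#' @param out_csv optional path for the difference-curve CSV.
#' @param a autoreceptor coefficients for the difference curves.
#' @param b heteroreceptor grid.
#' @param quiet suppress printing.
#' @return Invisibly, a list with `models` (see [canonical_models()]) and
#'   `differences` (a data frame with a `model` column).
#' @export
run_calibrate <- function(fixture = NULL, out_csv = NULL,
                          a = c(0, 0.1, 0.2), b = seq(0, 1, by = 0.05),
                          quiet = FALSE) {
  records <- if (is.null(fixture)) read_occupancy_table()
             else read_occupancy_table(fixture)
  models <- canonical_models(records)
  diffs <- do.call(rbind, lapply(c("model1", "model2"), function(mk) {
    d <- sz_hc_differences(models[[mk]], a = a, b = b)
    cbind(model = models[[mk]]$label, d)
  }))
  if (!is.null(out_csv)) utils::write.csv(diffs, out_csv, row.names = FALSE)
  if (!quiet) {
    cat(sprintf("Average healthy-control occupancy: %s\n",
                .fmt_pct(models$hc_average)))
    cat(sprintf("Extrapolated patient occupancy   : %s\n",
                .fmt_pct(models$sz_extrapolated)))
    for (mk in c("model1", "model2")) {
      m <- models[[mk]]
      cat(sprintf("%s: HC (B_max %.1f, P %s, Y %s)  SZ (B_max %.1f, P %s, Y %s)\n",
                  m$label,
                  m$hc$b_max, .fmt_pct(occupancy_from_da(m$hc$y)),
                  .fmt_y(m$hc$y),
                  m$sz$b_max, .fmt_pct(occupancy_from_da(m$sz$y)),
                  .fmt_y(m$sz$y)))
    }
    if (!is.null(out_csv))
      cat(sprintf("difference curves written to %s\n", out_csv))
  }
  invisible(list(models = models, differences = diffs))
}

#' Optimum-dose report
#'
#' Computes the optimum antipsychotic regimen under the net-binding
#' criterion for the requested canonical model(s) and optionally writes a
#' JSON report.
#'
#' @param model `"1"`, `"2"`, or `"both"`.
#' @param fixture optional occupancy CSV path.
#' @param json_out optional JSON output path.
#' @param quiet suppress printing.
#' @return Invisibly, a named list of [optimum_regimen()] results.
#' @export
run_optimum_dose <- function(model = "both", fixture = NULL, json_out = NULL,
                             quiet = FALSE) {
  model <- match.arg(as.character(model), c("1", "2", "both"))
  models <- if (is.null(fixture)) canonical_models()
            else canonical_models(read_occupancy_table(fixture))
  keys <- switch(model, "1" = "model1", "2" = "model2",
                 both = c("model1", "model2"))
  regs <- lapply(models[keys], optimum_regimen)
  if (!quiet) for (r in regs) print(r)
  if (!is.null(json_out)) {
    payload <- lapply(regs, function(r)
      list(f_over_k = r$f_over_k, p_apd = r$p_apd, p_da_apd = r$p_da_apd,
           p_total = r$p_total))
    jsonlite::write_json(payload, json_out, auto_unbox = TRUE, digits = NA)
    if (!quiet) cat(sprintf("report written to %s\n", json_out))
  }
  invisible(regs)
}

#' Clinical-outcome report
#'
#' Runs the depletion-response-to-PFC-activity transformation over a patient
#' record CSV (columns `beta`, `delta_panss_pos`) — or over a seeded
#' synthetic data set — and fits the symptom-change regression.  Rows with
#' infeasible `beta` values (too large for the assumed depletion) are
#' reported by row number.
#'
#' @param input_csv path to patient records; if `NULL`, synthetic records
#'   are generated.
#' @param alpha residual DA fraction.
#' @param a,b transformation D2 coefficients.
#' @param n,sigma,seed synthetic-mode settings (see
#'   [generate_outcome_records()]).
#' @param json_out optional JSON path for the regression summary.
#' @param quiet suppress printing.
#' @return Invisibly, the [fit_outcome_regression()] result.
#' @export
run_outcome <- function(input_csv = NULL, alpha = 0.3, a = 0, b = 0,
                        n = 14, sigma = 3, seed = 1, json_out = NULL,
                        quiet = FALSE) {
  if (is.null(input_csv)) {
    records <- generate_outcome_records(n = n, sigma = sigma, alpha = alpha,
                                        a = a, b = b, seed = seed)
  } else {
    records <- utils::read.csv(input_csv)
    if (!all(c("beta", "delta_panss_pos") %in% names(records)))
      stop("input CSV must have columns beta, delta_panss_pos",
           call. = FALSE)
    feas <- vapply(records$beta, function(bi)
      !inherits(tryCatch(estimate_da_from_bp_increase(bi, alpha),
                         error = identity), "error"), logical(1))
    if (any(!feas))
      stop("infeasible beta values in rows: ",
           paste(which(!feas), collapse = ", "), call. = FALSE)
  }
  fit <- fit_outcome_regression(records, alpha = alpha, a = a, b = b)
  if (!quiet) print(fit)
  if (!is.null(json_out)) {
    jsonlite::write_json(list(slope = fit$slope, intercept = fit$intercept,
                              r_squared = fit$r_squared,
                              p_value = fit$p_value, n = fit$n),
                         json_out, auto_unbox = TRUE, digits = NA)
    if (!quiet) cat(sprintf("report written to %s\n", json_out))
  }
  invisible(fit)
}

#' Reproduce the model's headline tables
#'
#' Convenience wrapper that prints the equilibrium reference block, the
#' calibration summary, and the optimum regimens in one pass.
#'
#' @param quiet suppress printing.
#' @return Invisibly, a list with the three sub-reports.
#' @export
reproduce_tables <- function(quiet = FALSE) {
  eq <- run_equilibrium_sweep(quiet = quiet)
  cal <- run_calibrate(quiet = quiet)
  dose <- run_optimum_dose(quiet = quiet)
  invisible(list(equilibrium = eq, calibration = cal, dose = dose))
}
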