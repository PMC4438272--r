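#' One-shot reproduction report
#'
#' Runs every analysis stage on a landscape and writes a machine-readable
#' JSON report plus a human-readable text summary: per-variant fold
#' decreases, single-residue removal/restoration panels, additivity gaps,
#' the functional-unit model fit with predictions for the untested
#' variants, the accessible-path census with borderline-edge sensitivity,
#' and the waiting-time quantities for the cooperative, stepwise, and
#' single-path models. Every number is produced by the corresponding
#' exported operation; the report layer does no arithmetic of its own.
#' Identical configurations produce byte-identical JSON.
#'
#' @param out_dir Output directory (created if needed).
#' @param table Optional path to a landscape TSV; default uses the packaged
#'   table.
#' @param wt_convention WT convention for the path analysis
#'   (\code{"observed"} default).
#' @param thresholds Fold cutoffs for the path census.
#' @param objective Unit-model objective for the headline fit
#'   (\code{"minimax"} default, matching the factor-of-two summary).
#' @param n,p Waiting-time chain size and per-step probability.
#' @return Invisibly, the report list. Side effects: writes
#'   \code{report.json} and \code{report.txt} under \code{out_dir}.
#' @export
reproduce_report <- function(out_dir, table = NULL,
                             wt_convention = c("observed", "chem_limited"),
                             thresholds = c(3, 5),
                             objective = c("minimax", "least_squares"),
                             n = 5L, p = 1 / 20) {
  wt_convention <- match.arg(wt_convention)
  objective <- match.arg(objective)
  landscape <- if (is.null(table)) builtin_table1(wt_convention)
               else load_landscape(table, wt_convention)

  folds <- vapply(landscape$genotype, function(g) {
    fold_decrease(landscape, g)$value
  }, numeric(1))
  fold_table <- data.frame(variant = landscape$variant,
                           kcat_km = landscape$kcat_km,
                           fold_decrease = unname(folds),
                           censor = landscape$censor,
                           provenance = landscape$provenance)

  removal <- vapply(ap_residues(), function(r) {
    removal_ratio(landscape, "11111", r, "chem_limited")$value
  }, numeric(1))
  restoration <- vapply(ap_residues(), function(r) {
    restoration_ratio(landscape, "00000", r)$value
  }, numeric(1))

  gap_rem <- interdependence_gap(landscape, mode = "removal_from_wt")
  gap_add <- interdependence_gap(landscape, mode = "addition_to_minimal")

  fit <- fit_units(landscape, objective = objective)
  missing_pred <- predict_missing(fit)

  census <- accessibility_report(landscape, thresholds, wt_convention)
  borderline <- attr(census, "borderline")

  coop <- mfpt_birth_death(cooperative_chain(n, p), method = "both")
  step <- mfpt_birth_death(stepwise_chain(n, p), method = "both")
  single <- single_path_time(n, p)
  on_landscape <- tryCatch(
    mfpt_general(landscape, thresholds[1], wt_convention, p),
    error = function(e) NULL)

  report <- list(
    schema_version = "1.0",
    config = list(table = if (is.null(table)) "builtin" else table,
                  wt_convention = wt_convention, thresholds = thresholds,
                  objective = objective, n = n, p = p),
    fold_decreases = fold_table,
    single_removal_from_wt = as.list(removal),
    single_restoration_to_minimal = as.list(restoration),
    additivity = list(
      removal_gap = gap_rem$value,
      removal_ddg_kcal_mol = abs(ddg_from_ratio(gap_rem)$value),
      addition_gap = gap_add$value,
      addition_ddg_kcal_mol = abs(ddg_from_ratio(gap_add)$value)
    ),
    unit_model = list(
      objective = objective,
      coefficients = as.list(unclass(stats::coef(fit))),
      max_fold_deviation = fit$max_fold_deviation,
      censored_within_bound = all(fit$censored$within_bound),
      predicted_missing = missing_pred
    ),
    paths = list(
      census = as.data.frame(census),
      borderline_edges = lapply(borderline, function(b) {
        b$from <- vapply(b$from, variant_name, character(1))
        b$to <- vapply(b$to, variant_name, character(1))
        b
      })
    ),
    waiting_times = list(
      cooperative = list(mfpt = coop$mfpt, half_time = coop$half_time),
      stepwise = list(mfpt = step$mfpt, half_time = step$half_time),
      single_path = list(mfpt = single$mfpt, half_time = single$half_time),
      landscape_chain = if (!is.null(on_landscape)) {
        list(threshold = thresholds[1], mfpt = on_landscape$mfpt,
             half_time = on_landscape$half_time)
      }
    )
  )

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  txt <- c(
    "Alkaline phosphatase active-site landscape report",
    "",
    sprintf("Variants: %d (%d measured, %d calculated, %d censored)",
            nrow(landscape), sum(landscape$provenance == "measured"),
            sum(landscape$provenance == "calculated"),
            sum(landscape$censor != "none")),
    sprintf("Additivity gap, removal mode: %.3g (ddG %.2f kcal/mol)",
            gap_rem$value, abs(ddg_from_ratio(gap_rem)$value)),
    sprintf("Additivity gap, addition mode: %.3g", gap_add$value),
    sprintf("Unit model (%s): max fold deviation %.3g",
            objective, fit$max_fold_deviation),
    "Predicted activities for untested variants:",
    sprintf("  %-28s %.3g (reference %.3g, %.2f-fold)",
            missing_pred$variant, missing_pred$predicted,
            missing_pred$reference, missing_pred$fold_vs_reference),
    "Accessible paths (strict > threshold):",
    sprintf("  >%g-fold: %d / 120 paths, %d / 80 edges",
            census$threshold, census$n_paths_accessible, census$n_edges_passing),
    "Waiting times (arbitrary units, half-time = ln2 x MFPT):",
    sprintf("  cooperative chain: MFPT %.3g, half-time %.3g", coop$mfpt, coop$half_time),
    sprintf("  stepwise chain:    MFPT %.3g, half-time %.3g", step$mfpt, step$half_time),
    sprintf("  single path:       MFPT %.3g, half-time %.3g", single$mfpt, single$half_time),
    if (!is.null(on_landscape)) {
      sprintf("  landscape chain (> %g-fold): MFPT %.3g, half-time %.3g",
              thresholds[1], on_landscape$mfpt, on_landscape$half_time)
    }
  )
  writeLines(txt, file.path(out_dir, "report.txt"))
  invisible(report)
}
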