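# Fold-effect and transition-state free-energy arithmetic over a landscape.
#
# All ratios are simple quotients of kcat/KM values; censoring (upper/lower
# limits) never changes the arithmetic but is propagated as a flag so that
# downstream consumers can report inequalities.

.gas_constant_kcal <- 1.9872e-3  # kcal mol^-1 K^-1

.effect_ratio <- function(value, numerator, denominator, censored) {
  structure(list(value = value, numerator_genotype = numerator,
                 denominator_genotype = denominator, censored = censored),
            class = "effect_ratio")
}

#' @export
print.effect_ratio <- function(x, ...) {
  cat(sprintf("%s / %s = %.3g%s\n",
              variant_name(x$numerator_genotype),
              variant_name(x$denominator_genotype),
              x$value, if (x$censored) " (censored)" else ""))
  invisible(x)
}

#' Fold decrease of a variant relative to the wild-type reference
#'
#' Reference activity divided by variant activity. The default reference is
#' the chemistry-limited WT estimate, matching the convention of the source
#' kinetic table in which the fold decrease of WT itself is one by
#' definition.
#'
#' @param landscape An \code{ap_landscape}.
#' @param genotype Genotype bitstring or variant name.
#' @param wt_convention WT reference convention, default
#'   \code{"chem_limited"}.
#' @return An \code{effect_ratio} with fields \code{value},
#'   \code{numerator_genotype}, \code{denominator_genotype}, \code{censored}.
#' @export
#' @examples
#' fold_decrease(builtin_table1(), "R166S")$value  # 6.3e3
fold_decrease <- function(landscape, genotype,
                          wt_convention = c("chem_limited", "observed")) {
  wt_convention <- match.arg(wt_convention)
  g <- parse_variant_name(genotype)
  ref <- landscape_activity(landscape, "11111", wt_convention)
  act <- landscape_activity(landscape, g, wt_convention)
  .effect_ratio(ref / act, "11111", g,
                .is_censored(landscape, g) || .is_censored(landscape, "11111"))
}

#' Rate effect of restoring one residue in a given background
#'
#' Activity of \code{background} with \code{residue} added, divided by the
#' activity of \code{background}. A value above one means restoration is
#' beneficial in that background.
#'
#' @inheritParams fold_decrease
#' @param background Genotype (bitstring or variant name) \emph{lacking}
#'   \code{residue}.
#' @param residue One of the five residue labels (see [ap_residues()]).
#' @param wt_convention WT reference convention; defaults to the landscape's.
#' @return An \code{effect_ratio}; \code{censored} is set when either
#'   endpoint is a censored record.
#' @export
#' @examples
#' ## restoring R166 with only D101 missing: ~170-fold
#' restoration_ratio(builtin_table1(), "D101A/R166S", "R166")$value
restoration_ratio <- function(landscape, background, residue,
                              wt_convention = NULL) {
  bg <- parse_variant_name(background)
  if (genotype_present(bg)[[residue]]) {
    stop(sprintf("residue %s is already present in background %s",
                 residue, variant_name(bg)), call. = FALSE)
  }
  to <- .genotype_with(bg, residue, TRUE)
  acts <- landscape_activity(landscape, c(to, bg), wt_convention)
  .effect_ratio(acts[1] / acts[2], to, bg,
                any(.is_censored(landscape, c(to, bg))))
}

#' Rate effect of removing one residue from a background
#'
#' Activity of \code{background} divided by the activity of
#' \code{background} with \code{residue} removed; the exact inverse of the
#' corresponding [restoration_ratio()].
#'
#' @inheritParams restoration_ratio
#' @param background Genotype \emph{containing} \code{residue}.
#' @return An \code{effect_ratio}.
#' @export
#' @examples
#' ## removing D101 from WT under the chemistry-limited reference: 64-fold
#' removal_ratio(builtin_table1(), "WT", "D101", wt_convention = "chem_limited")$value
removal_ratio <- function(landscape, background, residue,
                          wt_convention = NULL) {
  bg <- parse_variant_name(background)
  if (!genotype_present(bg)[[residue]]) {
    stop(sprintf("residue %s is absent from background %s",
                 residue, variant_name(bg)), call. = FALSE)
  }
  to <- .genotype_with(bg, residue, FALSE)
  acts <- landscape_activity(landscape, c(bg, to), wt_convention)
  .effect_ratio(acts[1] / acts[2], bg, to,
                any(.is_censored(landscape, c(to, bg))))
}

#' Convert a rate ratio to a transition-state free-energy difference
#'
#' Implements ddG = -RT ln(ratio) in kcal/mol with
#' R = 1.9872e-3 kcal mol^-1 K^-1, so a ratio of one maps to exactly zero
#' and ratios above one (observed faster than reference) give negative ddG.
#'
#' @param ratio An \code{effect_ratio} or a positive number.
#' @param temperature Kelvin; defaults to 298.15 (assays at 25 C).
#' @return A \code{ddg} object with fields \code{value} (kcal/mol),
#'   \code{temperature}, and \code{censored}.
#' @export
#' @examples
#' ddg_from_ratio(exp(1))$value  # -RT = -0.5925 kcal/mol
ddg_from_ratio <- function(ratio, temperature = 298.15) {
  censored <- FALSE
  if (inherits(ratio, "effect_ratio")) {
    censored <- ratio$censored
    ratio <- ratio$value
  }
  if (!is.numeric(ratio) || length(ratio) != 1L || !is.finite(ratio) || ratio <= 0) {
    stop("ratio must be a single positive finite number", call. = FALSE)
  }
  structure(list(value = -.gas_constant_kcal * temperature * log(ratio),
                 temperature = temperature, censored = censored),
            class = "ddg")
}

#' @export
print.ddg <- function(x, ...) {
  cat(sprintf("ddG = %.3g kcal/mol at %.2f K%s\n", x$value, x$temperature,
              if (isTRUE(x$censored)) " (from censored ratio: inequality)" else ""))
  invisible(x)
}

#' Additivity prediction for a combined variant
#'
#' Predicts the activity of the fully combined state assuming energetically
#' additive (multiplicative in rate) single-residue effects. In
#' \code{"removal_from_wt"} mode the WT reference is divided by the product
#' of the single-removal fold decreases; in \code{"addition_to_minimal"}
#' mode the minimal-enzyme activity is multiplied by the product of the
#' single-restoration ratios.
#'
#' @inheritParams fold_decrease
#' @param residues Character vector of residues to combine (default all
#'   five).
#' @param mode \code{"removal_from_wt"} or \code{"addition_to_minimal"}.
#' @param wt_convention WT reference, default \code{"chem_limited"} (the
#'   additivity analysis targets the chemical step).
#' @return List with \code{predicted} (M^-1 s^-1), \code{observed} for the
#'   combined genotype, \code{mode}, \code{censored}.
#' @export
additive_prediction <- function(landscape, residues = ap_residues(),
                                mode = c("removal_from_wt", "addition_to_minimal"),
                                wt_convention = c("chem_limited", "observed")) {
  mode <- match.arg(mode)
  wt_convention <- match.arg(wt_convention)
  stopifnot(length(residues) >= 1L, all(residues %in% ap_residues()))
  residues <- unique(residues)
  censored <- FALSE
  if (mode == "removal_from_wt") {
    base <- landscape_activity(landscape, "11111", wt_convention)
    combined <- Reduce(function(g, r) .genotype_with(g, r, FALSE), residues, "11111")
    prod_ratio <- 1
    for (r in residues) {
      rr <- removal_ratio(landscape, "11111", r, wt_convention)
      prod_ratio <- prod_ratio * rr$value
      censored <- censored || rr$censored
    }
    predicted <- base / prod_ratio
  } else {
    base <- landscape_activity(landscape, "00000", wt_convention)
    combined <- Reduce(function(g, r) .genotype_with(g, r, TRUE), residues, "00000")
    prod_ratio <- 1
    for (r in residues) {
      rr <- restoration_ratio(landscape, "00000", r, wt_convention)
      prod_ratio <- prod_ratio * rr$value
      censored <- censored || rr$censored
    }
    predicted <- base * prod_ratio
  }
  list(predicted = predicted,
       observed = landscape_activity(landscape, combined, wt_convention),
       combined_genotype = combined, mode = mode,
       censored = censored || .is_censored(landscape, combined))
}

#' Observed-over-predicted gap for a combined variant
#'
#' The ratio of the observed activity of the fully combined state to the
#' additivity prediction of [additive_prediction()]. A value of one means
#' the residues act independently; large deviations quantify energetic
#' interdependence.
#'
#' @inheritParams additive_prediction
#' @return An \code{effect_ratio} whose value is observed / predicted.
#' @export
#' @examples
#' ## all five residues, addition mode: WT is ~580-fold above prediction
#' interdependence_gap(builtin_table1(), mode = "addition_to_minimal")$value
interdependence_gap <- function(landscape, residues = ap_residues(),
                                mode = c("removal_from_wt", "addition_to_minimal"),
                                wt_convention = c("chem_limited", "observed")) {
  mode <- match.arg(mode)
  wt_convention <- match.arg(wt_convention)
  pred <- additive_prediction(landscape, residues, mode, wt_convention)
  out <- .effect_ratio(pred$observed / pred$predicted, pred$combined_genotype,
                       pred$combined_genotype, pred$censored)
  out$predicted <- pred$predicted
  out$observed <- pred$observed
  out
}

#' Double-mutant-cycle coupling free energy
#'
#' Interaction free energy between two residues in a fixed background,
#' computed over the four genotypes \{background, background+a,
#' background+b, background+a+b\}:
#' RT ln[(k_ab * k_0) / (k_a * k_b)]. Zero means the two residues contribute
#' independently; positive values indicate cooperativity (the pair together
#' is better than the product of the singles), negative values
#' anti-cooperativity.
#'
#' @inheritParams restoration_ratio
#' @param res_a,res_b Distinct residues absent from \code{background}.
#' @param background Genotype lacking both residues.
#' @return A \code{ddg}.
#' @export
#' @examples
#' ## D153 x K328 coupling with only the Mg2+ (E322) site present: ~+2.4 kcal/mol
#' cycle_coupling(builtin_table1(), "D153", "K328", "D101A/R166S/D153A/K328A")
cycle_coupling <- function(landscape, res_a, res_b, background,
                           wt_convention = NULL, temperature = 298.15) {
  bg <- parse_variant_name(background)
  if (res_a == res_b) stop("res_a and res_b must differ", call. = FALSE)
  pres <- genotype_present(bg)
  for (r in c(res_a, res_b)) {
    if (!r %in% ap_residues()) stop(sprintf("unknown residue '%s'", r), call. = FALSE)
    if (pres[[r]]) {
      stop(sprintf("residue %s overlaps the background %s", r, variant_name(bg)),
           call. = FALSE)
    }
  }
  ga <- .genotype_with(bg, res_a, TRUE)
  gb <- .genotype_with(bg, res_b, TRUE)
  gab <- .genotype_with(ga, res_b, TRUE)
  k <- landscape_activity(landscape, c(bg, ga, gb, gab), wt_convention)
  censored <- any(.is_censored(landscape, c(bg, ga, gb, gab)))
  val <- .gas_constant_kcal * temperature * log((k[4] * k[1]) / (k[2] * k[3]))
  structure(list(value = val, temperature = temperature, censored = censored,
                 genotypes = c(bg, ga, gb, gab)),
            class = "ddg")
}
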