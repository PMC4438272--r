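# The three-functional-unit multiplicative model of active-site energetics.
#
# Activity (log10 kcat/KM) is linear in ten parameters over presence
# indicators x_i of the five residues:
#
#   log10 k = beta0 + sum_i beta_i x_i
#           + x166 * (x101 * alpha_101 + x153 * alpha_153)   # D101/R166/D153
#           + x322 * x153 * x328 * gamma                      # D153/Mg/K328
#           + (x101 OR x322) * rho                            # D101/Mg redundancy
#
# beta0 is the log10 activity of the minimal enzyme; beta_i are base
# single-residue effects; alpha terms boost R166 when a flanking aspartate
# is present; gamma is the cooperative boost to the Mg2+ (E322) term when
# D153 and K328 are both present; rho is granted once if either member of
# the redundant D101/Mg2+ pair is present (inclusive OR:
# x101 + x322 - x101*x322).

.param_names <- c("beta0", "beta_101", "beta_166", "beta_153", "beta_322",
                  "beta_328", "alpha_101", "alpha_153", "gamma", "rho")

#' Construct a named unit-model parameter vector
#'
#' @param beta0 log10 baseline activity of the minimal enzyme.
#' @param beta_101,beta_166,beta_153,beta_322,beta_328 Per-residue base
#'   effects (log10 fold).
#' @param alpha_101,alpha_153 Boost to the R166 term when D101 / D153 is
#'   present (log10 fold).
#' @param gamma Cooperative boost to the Mg2+ (E322) term when D153 and K328
#'   are both present.
#' @param rho Redundancy term granted once when D101 or the Mg2+ ion (E322)
#'   is present.
#' @return Named numeric vector of length 10, class \code{unit_params}.
#' @export
unit_params <- function(beta0 = 0, beta_101 = 0, beta_166 = 0, beta_153 = 0,
                        beta_322 = 0, beta_328 = 0, alpha_101 = 0,
                        alpha_153 = 0, gamma = 0, rho = 0) {
  p <- c(beta0 = beta0, beta_101 = beta_101, beta_166 = beta_166,
         beta_153 = beta_153, beta_322 = beta_322, beta_328 = beta_328,
         alpha_101 = alpha_101, alpha_153 = alpha_153, gamma = gamma, rho = rho)
  stopifnot(all(is.finite(p)))
  structure(p, class = "unit_params")
}

.as_params <- function(x) {
  if (inherits(x, "unit_params")) return(x)
  stopifnot(is.numeric(x), length(x) == 10L)
  if (is.null(names(x))) names(x) <- .param_names
  stopifnot(setequal(names(x), .param_names))
  do.call(unit_params, as.list(x[.param_names]))
}

#' Unit-model design matrix
#'
#' One row per genotype, one column per parameter, such that the predicted
#' log10 activity is \code{unit_design(g) \%*\% params}.
#'
#' @param genotypes Character vector of bitstrings or variant names.
#' @return Numeric matrix with the ten parameter columns.
#' @export
unit_design <- function(genotypes = all_genotypes()) {
  g <- vapply(genotypes, parse_variant_name, character(1), USE.NAMES = FALSE)
  X <- t(vapply(g, function(b) {
    x <- as.integer(strsplit(b, "")[[1]])  # D101 R166 D153 E322 K328
    c(1, x[1], x[2], x[3], x[4], x[5],
      x[2] * x[1], x[2] * x[3],
      x[4] * x[3] * x[5],
      x[1] + x[4] - x[1] * x[4])
  }, numeric(10)))
  dimnames(X) <- list(g, .param_names)
  X
}

#' Predicted log10 activity under the unit model
#'
#' @param params A \code{unit_params} vector (or named numeric of length 10).
#' @param genotypes Genotypes to predict; defaults to all 32.
#' @return Named numeric vector of log10 kcat/KM values.
#' @export
#' @examples
#' p <- unit_params(beta0 = -0.77, beta_322 = 2.9)
#' predict_log_activity(p, c("00000", "01110"))
predict_log_activity <- function(params, genotypes = all_genotypes()) {
  params <- .as_params(params)
  drop(unit_design(genotypes) %*% as.numeric(params))
}

# assemble full parameter vector from free values + fixed values
.assemble <- function(free_vals, free, fixed) {
  p <- stats::setNames(numeric(10), .param_names)
  p[free] <- free_vals
  if (length(fixed)) p[names(fixed)] <- fixed
  p
}

#' Fit the functional-unit model to a landscape
#'
#' Fits the ten-parameter model in log10 space to the measured variants of a
#' landscape (the wild type enters at its chemistry-limited reference value,
#' since the model describes the chemical step). Censored upper-limit
#' records never enter the main objective; they contribute a one-sided
#' penalty only when the model predicts activity above the recorded bound.
#'
#' Two objectives are available: ordinary least squares (the default, used
#' for estimation) and minimax (Chebyshev), which minimises the largest
#' absolute log10 residual and is the criterion behind the "every variant
#' within a factor of two" summary. Both are deterministic: fitting starts
#' from the closed-form solution of the additive-only model (all four
#' interaction terms zero); the minimax objective is solved by a smooth
#' log-sum-exp homotopy (convex in the parameters) whose sharpness is
#' increased until the smoothing error is far below the reported precision.
#'
#' @param landscape An \code{ap_landscape}.
#' @param objective \code{"least_squares"} or \code{"minimax"}.
#' @param include_censored Include the one-sided censored penalty
#'   (default TRUE).
#' @param fixed Optional named numeric vector of parameters to hold fixed
#'   (e.g. \code{c(rho = 0)}).
#' @return A \code{unit_fit} object with components \code{coefficients},
#'   \code{fitted_log10} (all 32 genotypes), \code{deviation} (per measured
#'   non-censored variant: observed, predicted, fold deviation
#'   \code{max(pred/obs, obs/pred)}), \code{max_fold_deviation},
#'   \code{censored} (bound vs prediction for censored records),
#'   \code{objective}, \code{objective_value}, and the fitting
#'   \code{landscape}. Supports \code{print}, \code{summary}, \code{coef},
#'   \code{predict}, \code{fitted}, \code{residuals}, \code{plot}, and
#'   \code{simulate} methods.
#' @seealso [predict_missing()], [generate_landscape()]
#' @export
#' @examples
#' fit <- fit_units(builtin_table1(), objective = "minimax")
#' fit$max_fold_deviation
fit_units <- function(landscape, objective = c("least_squares", "minimax"),
                      include_censored = TRUE, fixed = NULL) {
  objective <- match.arg(objective)
  stopifnot(inherits(landscape, "ap_landscape"))
  if (length(fixed)) {
    stopifnot(is.numeric(fixed), !is.null(names(fixed)),
              all(names(fixed) %in% .param_names))
  }
  free <- setdiff(.param_names, names(fixed))

  meas <- landscape$provenance == "measured" & landscape$censor == "none"
  cens <- landscape$provenance == "measured" & landscape$censor == "upper_limit"
  g_meas <- landscape$genotype[meas]
  y <- log10(landscape_activity(landscape, g_meas, "chem_limited"))
  X <- unit_design(g_meas)
  g_cens <- landscape$genotype[cens]
  yc <- log10(landscape$kcat_km[cens])
  Xc <- unit_design(g_cens)
  use_cens <- include_censored && length(g_cens) > 0L
  offset <- if (length(fixed)) drop(X[, names(fixed), drop = FALSE] %*% fixed) else 0
  offset_c <- if (length(fixed) && use_cens) {
    drop(Xc[, names(fixed), drop = FALSE] %*% fixed)
  } else 0

  # deterministic initialization: closed-form additive-only solution
  add_cols <- intersect(free, .param_names[1:6])
  init <- stats::setNames(numeric(length(free)), free)
  if (length(add_cols)) {
    fit0 <- stats::lm.fit(X[, add_cols, drop = FALSE], y - offset)
    init[add_cols] <- fit0$coefficients
  }

  resid_all <- function(b) {
    p <- .assemble(b, free, fixed)
    list(r = drop(X[, free, drop = FALSE] %*% b) + offset - y,
         rc = if (use_cens) drop(Xc[, free, drop = FALSE] %*% b) + offset_c - yc
              else numeric(0))
  }

  if (objective == "least_squares") {
    # exact closed form when the censored bound is not violated
    ls <- stats::lm.fit(X[, free, drop = FALSE], y - offset)
    b <- ls$coefficients
    rr <- resid_all(b)
    if (use_cens && any(rr$rc > 1e-12)) {
      obj <- function(b) {
        rr <- resid_all(b)
        sum(rr$r^2) + sum(pmax(rr$rc, 0)^2)
      }
      grad <- function(b) {
        rr <- resid_all(b)
        g <- 2 * drop(crossprod(X[, free, drop = FALSE], rr$r))
        if (length(rr$rc)) {
          g <- g + 2 * drop(crossprod(Xc[, free, drop = FALSE], pmax(rr$rc, 0)))
        }
        g
      }
      opt <- stats::optim(b, obj, grad, method = "BFGS",
                          control = list(maxit = 2000, reltol = 1e-15))
      if (opt$convergence != 0) {
        stop("least-squares solver did not converge: ", opt$message, call. = FALSE)
      }
      b <- opt$par
    }
    objective_value <- {rr <- resid_all(b); sum(rr$r^2) + sum(pmax(rr$rc, 0)^2)}
  } else {
    # Chebyshev fit by log-sum-exp homotopy: f_k -> max(|r|, rc) as k grows
    softmax_obj <- function(b, k) {
      rr <- resid_all(b)
      z <- c(k * rr$r, -k * rr$r, k * rr$rc)
      m <- max(z)
      (m + log(sum(exp(z - m)))) / k
    }
    softmax_grad <- function(b, k) {
      rr <- resid_all(b)
      z <- c(k * rr$r, -k * rr$r, k * rr$rc)
      m <- max(z)
      w <- exp(z - m); w <- w / sum(w)
      n <- length(rr$r)
      gm <- drop(crossprod(X[, free, drop = FALSE], w[1:n] - w[(n + 1):(2 * n)]))
      if (length(rr$rc)) {
        gm <- gm + drop(crossprod(Xc[, free, drop = FALSE],
                                  w[(2 * n + 1):length(w)]))
      }
      gm
    }
    b <- init
    ls <- stats::lm.fit(X[, free, drop = FALSE], y - offset)
    b[] <- ls$coefficients
    for (k in c(2, 5, 10, 20, 50, 100, 200, 500, 1000, 2000, 5000)) {
      opt <- stats::optim(b, softmax_obj, softmax_grad, k = k, method = "BFGS",
                          control = list(maxit = 2000, reltol = 1e-15))
      if (opt$convergence > 1) {
        stop("minimax solver did not converge at sharpness ", k, call. = FALSE)
      }
      b <- opt$par
    }
    rr <- resid_all(b)
    objective_value <- max(abs(rr$r), rr$rc)
  }

  params <- .as_params(.assemble(b, free, fixed))
  fitted_log10 <- predict_log_activity(params)
  pred_meas <- fitted_log10[g_meas]
  fold_dev <- 10^abs(pred_meas - y)
  deviation <- data.frame(
    genotype = g_meas,
    variant = vapply(g_meas, variant_name, character(1)),
    observed = 10^y, predicted = 10^pred_meas,
    fold_deviation = fold_dev, row.names = NULL, stringsAsFactors = FALSE
  )
  censored_tab <- data.frame(
    genotype = g_cens,
    variant = vapply(g_cens, variant_name, character(1)),
    bound = 10^yc, predicted = 10^fitted_log10[g_cens],
    within_bound = fitted_log10[g_cens] <= yc,
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(list(coefficients = params, objective = objective,
                 objective_value = objective_value,
                 fitted_log10 = fitted_log10, deviation = deviation,
                 max_fold_deviation = max(fold_dev),
                 censored = censored_tab, fixed = fixed,
                 include_censored = include_censored,
                 landscape = landscape),
            class = "unit_fit")
}

#' @export
print.unit_fit <- function(x, ...) {
  cat(sprintf("Functional-unit model fit (%s objective)\n", x$objective))
  cat(sprintf("  %d measured variants; max fold deviation %.3g\n",
              nrow(x$deviation), x$max_fold_deviation))
  if (nrow(x$censored)) {
    plural <- nrow(x$censored) > 1
    cat(sprintf("  censored record%s %s the recorded bound\n",
                if (plural) "s" else "",
                paste0(if (all(x$censored$within_bound)) "respect" else "VIOLATE",
                       if (plural) "" else "s")))
  }
  cat("Coefficients (log10 units):\n")
  print(round(unclass(stats::coef(x)), 4))
  invisible(x)
}

#' @export
coef.unit_fit <- function(object, ...) object$coefficients

#' @export
fitted.unit_fit <- function(object, ...) object$fitted_log10

#' @export
residuals.unit_fit <- function(object, ...) {
  stats::setNames(log10(object$deviation$predicted) -
                    log10(object$deviation$observed),
                  object$deviation$genotype)
}

#' Predict activities from a fitted unit model
#'
#' @param object A \code{unit_fit}.
#' @param genotypes Genotypes to predict (default all 32).
#' @param type \code{"activity"} (M^-1 s^-1) or \code{"log10"}.
#' @param ... Unused.
#' @return Named numeric vector of predictions.
#' @export
predict.unit_fit <- function(object, genotypes = all_genotypes(),
                             type = c("activity", "log10"), ...) {
  type <- match.arg(type)
  p <- predict_log_activity(stats::coef(object), genotypes)
  if (type == "activity") 10^p else p
}

#' @export
summary.unit_fit <- function(object, ...) {
  out <- list(fit = object,
              deviation = object$deviation[order(-object$deviation$fold_deviation), ])
  class(out) <- "summary.unit_fit"
  out
}

#' @export
print.summary.unit_fit <- function(x, ...) {
  print(x$fit)
  cat("\nPer-variant deviations (worst first):\n")
  print(x$deviation, digits = 3, row.names = FALSE)
  invisible(x)
}

#' @export
plot.unit_fit <- function(x, ...) {
  d <- x$deviation
  graphics::plot(log10(d$observed), log10(d$predicted),
                 xlab = "observed log10 kcat/KM", ylab = "predicted log10 kcat/KM",
                 main = "Functional-unit model", ...)
  graphics::abline(0, 1, col = "grey40")
  graphics::abline(log10(2), 1, lty = 2, col = "grey70")
  graphics::abline(-log10(2), 1, lty = 2, col = "grey70")
  invisible(x)
}

#' Simulate synthetic landscapes from a fitted unit model
#'
#' Convenience wrapper around [generate_landscape()] using the fitted
#' coefficients as the true parameters.
#'
#' @param object A \code{unit_fit}.
#' @param nsim Number of landscapes.
#' @param seed Integer seed (required for reproducibility).
#' @param noise_sd_log10,n_replicates Passed to [synthetic_spec()].
#' @param ... Unused.
#' @return List of \code{nsim} \code{ap_landscape} objects.
#' @export
simulate.unit_fit <- function(object, nsim = 1, seed, noise_sd_log10 = 0.15,
                              n_replicates = 2, ...) {
  stopifnot(!missing(seed))
  lapply(seq_len(nsim), function(i) {
    generate_landscape(synthetic_spec(
      true_params = stats::coef(object), noise_sd_log10 = noise_sd_log10,
      n_replicates = n_replicates, seed = seed + i - 1L))
  })
}

#' Model predictions for the untested (calculated) variants
#'
#' Returns the fitted model's predictions for every record whose provenance
#' is \code{calculated} (in the packaged table: the four combinations that
#' were never expressed), alongside the reference values carried by the
#' landscape and the fold ratio between the two.
#'
#' @param fit A \code{unit_fit}.
#' @param landscape Landscape supplying the calculated records; defaults to
#'   the one the model was fit to.
#' @return Data.frame with \code{variant}, \code{predicted},
#'   \code{reference}, \code{fold_vs_reference} (\code{max(p/r, r/p)}).
#' @export
#' @examples
#' predict_missing(fit_units(builtin_table1()))
predict_missing <- function(fit, landscape = fit$landscape) {
  stopifnot(inherits(fit, "unit_fit"), inherits(landscape, "ap_landscape"))
  calc <- landscape[landscape$provenance == "calculated", ]
  pred <- predict.unit_fit(fit, calc$genotype)
  data.frame(
    genotype = calc$genotype, variant = calc$variant,
    predicted = unname(pred), reference = calc$kcat_km,
    fold_vs_reference = unname(pmax(pred / calc$kcat_km, calc$kcat_km / pred)),
    row.names = NULL, stringsAsFactors = FALSE
  )
}
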