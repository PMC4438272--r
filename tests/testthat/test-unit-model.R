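test_that("the model algebra gates each interaction on the right residues", {
  p <- random_params(3)
  # minimal enzyme: baseline only
  expect_identical(unname(predict_log_activity(p, "00000")), p[["beta0"]])
  # alpha terms contribute only when R166 is present
  with_r166 <- unname(predict_log_activity(p, "11100"))
  without_r166 <- unname(predict_log_activity(p, "10100"))
  expect_equal(with_r166 - without_r166,
               p[["beta_166"]] + p[["alpha_101"]] + p[["alpha_153"]])
  # gamma contributes only when E322 (Mg2+) is present alongside D153 and K328
  expect_equal(unname(predict_log_activity(p, "00111") - predict_log_activity(p, "00110")),
               p[["beta_328"]] + p[["gamma"]])
  expect_equal(unname(predict_log_activity(p, "00101") - predict_log_activity(p, "00100")),
               p[["beta_328"]])
  # rho is granted once if either D101 or E322 is present, not twice
  base <- unname(predict_log_activity(p, "00000"))
  d101 <- unname(predict_log_activity(p, "10000"))
  e322 <- unname(predict_log_activity(p, "00010"))
  both <- unname(predict_log_activity(p, "10010"))
  expect_equal(d101 - base, p[["beta_101"]] + p[["rho"]])
  expect_equal(e322 - base, p[["beta_322"]] + p[["rho"]])
  expect_equal(both - base, p[["beta_101"]] + p[["beta_322"]] + p[["rho"]])
  # zero interactions reduce to an additive model
  add <- additive_params()
  ls0 <- generate_landscape(synthetic_spec(add, noise_sd_log10 = 0, seed = 5))
  expect_equal(interdependence_gap(ls0, mode = "removal_from_wt")$value, 1,
               tolerance = 1e-10)
})

test_that("noiseless synthetic landscapes give exact parameter recovery", {
  for (seed in 1:3) {
    p <- random_params(seed)
    ls0 <- generate_landscape(synthetic_spec(p, noise_sd_log10 = 0, seed = seed))
    fit <- fit_units(ls0, objective = "least_squares")
    expect_lt(max(abs(as.numeric(coef(fit)) - as.numeric(p))), 1e-6)
    expect_lt(fit$max_fold_deviation, 1 + 1e-9)
  }
})

test_that("the published-table fit reproduces every measured variant within ~2-fold", {
  fit <- fit_units(table1, objective = "minimax")
  expect_lte(signif(fit$max_fold_deviation, 2), 2)
  expect_equal(nrow(fit$deviation), 27L)  # 26 mutant records + WT
  expect_true(all(fit$deviation$fold_deviation >= 1))
  # the censored quadruple mutant is flagged separately and respects its bound
  expect_equal(fit$censored$variant, "D101A/R166S/E322Y/K328A")
  expect_true(all(fit$censored$within_bound))
  # least squares has a smaller SSR but a larger extreme deviation here
  fit_ls <- fit_units(table1, objective = "least_squares")
  expect_gte(fit_ls$max_fold_deviation, fit$max_fold_deviation)
})

test_that("dropping the redundancy term strictly degrades the fit", {
  full <- fit_units(table1, objective = "minimax")
  no_rho <- fit_units(table1, objective = "minimax", fixed = c(rho = 0))
  expect_gt(no_rho$max_fold_deviation, full$max_fold_deviation)
  # nested-model monotonicity: freeing any interaction term never hurts
  for (term in c("alpha_101", "alpha_153", "gamma", "rho")) {
    restricted <- fit_units(table1, objective = "minimax",
                            fixed = stats::setNames(0, term))
    expect_gte(restricted$objective_value, full$objective_value - 1e-9)
  }
})

test_that("the fitted model predicts the four untested variants near their table values", {
  fit <- fit_units(table1, objective = "least_squares")
  mp <- predict_missing(fit)
  expect_setequal(mp$variant, c("D101A/K328A", "D101A/R166S/E322Y",
                                "D101A/R166S/K328A", "D101A/D153A/E322Y"))
  expect_true(all(mp$fold_vs_reference <= 2.5))
})

test_that("the fitted parameters imply the couplings the units describe", {
  fit <- fit_units(table1, objective = "least_squares")
  modeled <- new_landscape(data.frame(genotype = all_genotypes(),
                                      kcat_km = 10^unname(fitted(fit)),
                                      stringsAsFactors = FALSE))
  RT <- 1.9872e-3 * 298.15
  # no residual R166 x K328 coupling is possible under the model
  expect_equal(cycle_coupling(modeled, "R166", "K328", "00000")$value, 0,
               tolerance = 1e-10)
  # D153 x K328 coupling with Mg2+ present equals RT ln(10^gamma)
  expect_equal(cycle_coupling(modeled, "D153", "K328", "00010")$value,
               RT * log(10) * coef(fit)[["gamma"]], tolerance = 1e-10)
  # D101 x E322 coupling equals the anti-cooperative -RT ln(10^rho)
  expect_equal(cycle_coupling(modeled, "D101", "E322", "00000")$value,
               -RT * log(10) * coef(fit)[["rho"]], tolerance = 1e-10)
})

test_that("unit_fit methods are coherent", {
  fit <- fit_units(table1)
  expect_s3_class(fit, "unit_fit")
  expect_named(coef(fit), apsite:::.param_names)
  expect_length(fitted(fit), 32L)
  expect_equal(unname(predict(fit, "00000", type = "log10")),
               coef(fit)[["beta0"]])
  expect_equal(10^predict(fit, "WT", type = "log10"),
               predict(fit, "WT", type = "activity"), ignore_attr = TRUE)
  r <- residuals(fit)
  expect_length(r, 27L)
  expect_equal(max(10^abs(r)), fit$max_fold_deviation)
  expect_output(print(fit), "max fold deviation")
  expect_output(print(summary(fit)), "Per-variant deviations")
  sims <- simulate(fit, nsim = 2, seed = 7)
  expect_length(sims, 2L)
  expect_s3_class(sims[[1]], "ap_landscape")
  expect_false(isTRUE(all.equal(sims[[1]]$kcat_km, sims[[2]]$kcat_km)))
})
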