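test_that("fold decreases reproduce the published single-mutant effects", {
  expect_equal(fold_decrease(table1, "R166S")$value, 6.3e3)
  expect_equal(signif(fold_decrease(table1, "E322Y")$value, 2), 8.8e4)
  expect_equal(signif(fold_decrease(table1, "00000")$value, 2), 3.7e9)
  expect_identical(fold_decrease(table1, "WT")$value, 1)
  # under the observed convention WT is 3.3e7 / 3.3e7
  expect_identical(fold_decrease(table1, "WT", "observed")$value, 1)
})

test_that("restoration and removal ratios match the published panels", {
  # R166 restored with D153 present (D101 absent): ~170-fold
  expect_equal(signif(restoration_ratio(table1, "D101A/R166S", "R166")$value, 2), 170)
  # R166 restored with D101 present (D153 absent): ~220-fold
  expect_equal(signif(restoration_ratio(table1, "D153A/R166S", "R166")$value, 2), 220)
  # Mg2+ restored in the D101-only background: ~820-fold
  expect_equal(signif(
    restoration_ratio(table1, "R166S/D153A/E322Y/K328A", "E322")$value, 2), 820)
  # D153 alone is deleterious; the ratio uses the censored bound and is flagged
  r <- restoration_ratio(table1, "00000", "D153")
  expect_true(r$censored)
  expect_equal(signif(r$value, 2), 0.12)
  # removal from WT under the chemistry-limited reference
  expect_equal(removal_ratio(table1, "WT", "D101", wt_convention = "chem_limited")$value,
               6.3e8 / 9.9e6)
  expect_equal(signif(removal_ratio(table1, "WT", "E322", wt_convention = "chem_limited")$value, 2),
               8.8e4)
  # remove-then-restore is an exact inverse pair
  for (r in ap_residues()) {
    rem <- removal_ratio(table1, "WT", r)
    res <- restoration_ratio(table1, apsite:::.genotype_with("11111", r, FALSE), r)
    expect_equal(rem$value / res$value, 1, tolerance = 1e-12)
  }
  # domain errors
  expect_error(restoration_ratio(table1, "WT", "D101"), "already present")
  expect_error(removal_ratio(table1, "00000", "D101"), "absent")
})

test_that("ddG conversion follows -RT ln(ratio) with R = 1.9872e-3", {
  expect_identical(ddg_from_ratio(1)$value, 0)
  expect_equal(ddg_from_ratio(exp(1))$value, -1.9872e-3 * 298.15, tolerance = 1e-12)
  expect_equal(ddg_from_ratio(exp(1), temperature = 100)$value, -1.9872e-3 * 100,
               tolerance = 1e-12)
  expect_error(ddg_from_ratio(0), "positive")
  expect_error(ddg_from_ratio(-2), "positive")
  # censoring propagates through conversion
  expect_true(ddg_from_ratio(restoration_ratio(table1, "00000", "D153"))$censored)
})

test_that("additivity predictions quantify the published interdependence", {
  # removing all five: prediction falls ~1.8e6-fold below the observed minimal
  gap_rem <- interdependence_gap(table1, mode = "removal_from_wt")
  expect_equal(signif(gap_rem$value, 2), 1.8e6)
  # corresponding free-energy gap ~8.5 kcal/mol at recomputed precision
  expect_equal(abs(ddg_from_ratio(gap_rem)$value), 8.53, tolerance = 0.01)
  # adding all five back: observed WT is ~580-fold above the prediction
  gap_add <- interdependence_gap(table1, mode = "addition_to_minimal")
  expect_equal(signif(gap_add$value, 2), 580)
  expect_true(gap_add$censored)  # D153-alone bound enters the product
  # single-residue prediction is exact by construction
  one <- additive_prediction(table1, "R166", mode = "addition_to_minimal")
  expect_equal(one$predicted, one$observed, tolerance = 1e-12)
})

test_that("double-mutant cycles recover the published couplings", {
  # D153 x K328 with only the Mg2+ site present: cooperative, ~+2.4 kcal/mol
  cc <- cycle_coupling(table1, "D153", "K328", "D101A/R166S/D153A/K328A")
  expect_equal(cc$value, 2.40, tolerance = 0.01)
  # symmetric in the two residues
  cc2 <- cycle_coupling(table1, "K328", "D153", "D101A/R166S/D153A/K328A")
  expect_equal(cc$value, cc2$value, tolerance = 1e-12)
  # D101 and K328 are essentially independent: |coupling| <= RT ln 2
  cc3 <- cycle_coupling(table1, "D101", "K328", "00000")
  expect_lte(abs(cc3$value), 1.9872e-3 * 298.15 * log(2))
  expect_error(cycle_coupling(table1, "D101", "D101", "00000"), "differ")
  expect_error(cycle_coupling(table1, "D101", "R166", "D153A"), "overlaps")
})

test_that("removal ratios telescope: any order of removals gives the same total", {
  residues <- c("D101", "D153", "K328")
  orders <- list(residues, rev(residues), residues[c(2, 1, 3)])
  totals <- vapply(orders, function(ord) {
    g <- "11111"
    total <- 1
    for (r in ord) {
      total <- total * removal_ratio(table1, g, r)$value
      g <- apsite:::.genotype_with(g, r, FALSE)
    }
    total
  }, numeric(1))
  expect_equal(totals, rep(totals[1], length(totals)), tolerance = 1e-12)
})

test_that("every hypercube 2-face is consistent: alternating edge ratios cancel", {
  for (g in all_genotypes()) {
    absent <- ap_residues()[!genotype_present(g)]
    if (length(absent) < 2) next
    pairs <- utils::combn(absent, 2, simplify = FALSE)
    for (ab in pairs) {
      up_a <- restoration_ratio(table1, g, ab[1])$value
      a_then_b <- restoration_ratio(
        table1, apsite:::.genotype_with(g, ab[1], TRUE), ab[2])$value
      up_b <- restoration_ratio(table1, g, ab[2])$value
      b_then_a <- restoration_ratio(
        table1, apsite:::.genotype_with(g, ab[2], TRUE), ab[1])$value
      expect_equal(up_a * a_then_b / (up_b * b_then_a), 1, tolerance = 1e-12)
    }
  }
})

test_that("interaction-free synthetic landscapes show no interdependence", {
  sp <- synthetic_spec(additive_params(), noise_sd_log10 = 0, seed = 11)
  flat <- generate_landscape(sp)
  for (mode in c("removal_from_wt", "addition_to_minimal")) {
    expect_equal(interdependence_gap(flat, mode = mode)$value, 1,
                 tolerance = 1e-10)
    # subsets too
    expect_equal(
      interdependence_gap(flat, c("D101", "E322"), mode = mode)$value, 1,
      tolerance = 1e-10)
  }
  pairs <- utils::combn(ap_residues(), 2, simplify = FALSE)
  for (ab in pairs) {
    cc <- cycle_coupling(flat, ab[1], ab[2],
                         Reduce(function(g, r) apsite:::.genotype_with(g, r, FALSE),
                                ab, "11111"))
    expect_equal(cc$value, 0, tolerance = 1e-10)
  }
})
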