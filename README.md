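# apsite

Energetics of the *Escherichia coli* alkaline phosphatase (AP) active-site
residue network: analysis tools for the complete 2^5 combinatorial mutant
landscape of the five catalytic-network residues D101, R166, D153, E322
(whose carboxylate ligates the catalytic Mg²⁺ ion) and K328.

AP is one of the most proficient enzymes known, and these five side chains
form a hydrogen-bonded, metal-coordinating network around the transferred
phosphoryl group. The package is for enzymologists and molecular-evolution
researchers who want to ask, quantitatively: do such network residues act
independently, fully cooperatively, or something in between — and what does
the answer imply for how an active site can evolve?

All activities are catalytic efficiencies, k_cat/K_M (M⁻¹ s⁻¹), the
free-enzyme rate constant for which the chemical step is rate limiting
across the variant set. A genotype is the subset of wild-type residues
present, rendered as a bitstring over the order D101, R166, D153, E322,
K328 (`"11111"` = WT, `"00000"` = the minimal quintuple mutant).

## What it computes

* **Landscape I/O** — `builtin_table1()` ships all 32 variants (27 measured
  plus WT, one upper-limit record, four model-derived entries);
  `load_landscape()` / `write_landscape()` read and write the TSV dialect.
* **Fold-effect and ΔΔG‡ arithmetic** — `fold_decrease()`,
  `removal_ratio()`, `restoration_ratio()`, and
  `ddg_from_ratio()` implementing ΔΔG‡ = −RT ln(ratio);
  `additive_prediction()` and `interdependence_gap()` test energetic
  additivity, k_rel,predicted = Π k_rel,i; `cycle_coupling()` computes
  double-mutant-cycle interaction energies RT ln[(k_ab·k_∅)/(k_a·k_b)].
* **The functional-unit model** — `fit_units()` fits a ten-parameter
  log-linear model with three interaction motifs: near-additive positioning
  of R166 by D101 and D153 (`alpha_101`, `alpha_153`), cooperative
  enhancement of the Mg²⁺ contribution by D153 and K328 (`gamma`), and an
  anti-cooperative (redundant, OR-gated) D101/Mg²⁺ term (`rho`):

  ```
  log10 k = beta0 + Σ beta_i x_i
          + x_R166 (x_D101 alpha_101 + x_D153 alpha_153)
          + x_E322 x_D153 x_K328 gamma
          + (x_D101 ∨ x_E322) rho
  ```

  Objectives: least squares (estimation) or minimax/Chebyshev (the
  "every variant within a factor of two" criterion). `predict_missing()`
  reports the model's predictions for the four variants never expressed.
* **Evolutionary accessibility** — `enumerate_monotonic_paths()` and
  `count_paths_dp()` count the orderings of the five restorations (out of
  5! = 120) in which every step increases activity by strictly more than a
  fold threshold; `accessibility_report()` adds borderline-edge sensitivity.
* **Waiting times** — birth–death mean first-passage times for the fully
  cooperative chain (all five residues must drift in before any advantage),
  the stepwise chain (every acquisition is advantageous and irreversible),
  the single-pathway model, and the landscape-specific chain
  (`mfpt_general()`); `simulate_chain()` is a kinetic Monte Carlo oracle.
* **Synthetic data** — `generate_landscape()` simulates landscapes from
  known unit parameters with log-normal measurement noise;
  `recovery_experiment()` benchmarks parameter recovery.
* **One-shot report** — `reproduce_report()` writes the whole analysis as
  JSON + text.

## Worked example

```r
library(apsite)
ap <- builtin_table1()

fold_decrease(ap, "R166S")
#> WT / R166S = 6.3e+03

restoration_ratio(ap, "D101A/R166S", "R166")
#> D101A / D101A/R166S = 171

cycle_coupling(ap, "D153", "K328", "D101A/R166S/D153A/K328A")
#> ddG = 2.4 kcal/mol at 298.15 K

fit <- fit_units(ap, objective = "minimax")
fit
#> Functional-unit model fit (minimax objective)
#>   27 measured variants; max fold deviation 2.04
#>   censored record respects the recorded bound
#> Coefficients (log10 units):
#>     beta0  beta_101  beta_166  beta_153  beta_322  beta_328 alpha_101 alpha_153
#>   -0.8833   -0.1261    0.8938   -1.2414    3.1577    0.6103    1.3101    1.4024
#>     gamma       rho
#>    1.7649    1.6011

enumerate_monotonic_paths(ap, 3)
#> Path census at >3-fold (WT convention: observed):
#>   35 / 120 orderings accessible; 62 / 80 edges pass

mfpt_birth_death(cooperative_chain(5, 1/20), method = "both")
#> Mean first-passage time 6.829e+05 (half-time 4.733e+05) [both]
#>   (arbitrary time units)

mfpt_general(ap, threshold = 3)
#> Mean first-passage time 59.17 (half-time 41.01) [linear_solve]
#>   (arbitrary time units)
```

Reading these numbers: removing R166 costs 6,300-fold relative to the
chemistry-limited WT reference, but restoring it when D101 is absent
recovers only ~170-fold — its effectiveness depends on the flanking
aspartates. D153 and K328 couple cooperatively (+2.4 kcal/mol) through the
Mg²⁺ site. The ten-parameter unit model reproduces every measured variant
within a factor of ~2. At a strict >3-fold selective-advantage cutoff, 35
of the 120 possible restoration orders are monotonically uphill, so the
landscape-specific mean waiting time (half-time 41, arbitrary units) sits
between the stepwise (32) and single-pathway (69) extremes — roughly four
orders of magnitude faster than the fully cooperative chain (4.7 × 10⁵).

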