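---
title: "Methods: energetics and evolution of the AP active-site network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: energetics and evolution of the AP active-site network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apsite)
```

## The system and the question

The *E. coli* alkaline phosphatase active site contains, beyond the Zn²⁺
ions and the S102 nucleophile, a hydrogen-bonded and metal-coordinating
network of five groups: D101, R166, D153, the Mg²⁺ ion held by E322, and
K328. Replacing E322 with tyrosine both removes the carboxylate and
sterically blocks Mg²⁺ binding, so absence of E322 is treated throughout as
absence of the Mg²⁺ ion. Each position is binary — wild-type side chain
present or ablated (D101A, R166S, D153A, E322Y, K328A; alternative
ablations at each position behave equivalently and are accepted as aliases)
— giving 2⁵ = 32 genotypes.

The single fitness-like quantity is k~cat~/K~M~ for phosphate monoester
hydrolysis (M⁻¹ s⁻¹), the free-enzyme second-order rate constant. It is the
only rate constant used because the chemical step is rate limiting for
k~cat~/K~M~ across the variant set, whereas k~cat~ is limited by product
release for the fast variants. Two wild-type reference values coexist:

* **observed**: 3.3 × 10⁷ M⁻¹ s⁻¹, which is partly association-limited, and
* **chemistry-limited**: 6.3 × 10⁸ M⁻¹ s⁻¹, the value expected were the
  chemical step rate limiting for WT too. This constant is taken as given.

Fold *decreases* and the unit-model fit use the chemistry-limited reference
(so the WT fold decrease is exactly one and the model describes the
chemical step); path accessibility defaults to the observed value, i.e. the
landscape as measured. Every operation accepts an explicit override, and
`accessibility_report()` makes the sensitivity of path counts to this
choice auditable.

## Ratio and free-energy conventions

All effects are ratios of activities. `ddg_from_ratio()` implements
ΔΔG‡ = −RT ln(ratio) with R = 1.9872 × 10⁻³ kcal mol⁻¹ K⁻¹ at 298.15 K
(assays at 25 °C), so a ratio of one is exactly 0 kcal/mol and a
beneficial ratio (> 1) has negative ΔΔG‡. Reports quote the magnitude where
a gap is described qualitatively. Double-mutant-cycle couplings follow
RT ln[(k~ab~·k~∅~)/(k~a~·k~b~)]: positive = cooperative, negative =
anti-cooperative, zero = independent.

One record — the quadruple mutant retaining only D153 — is an upper limit
(k~cat~/K~M~ ≤ 2.0 × 10⁻² M⁻¹ s⁻¹). Censoring never changes arithmetic:
ratios are computed at the nominal bound and a `censored` flag is
propagated so consumers can present the result as an inequality. This
mirrors the qualitative statement the bound supports (D153 alone is
deleterious by *at least* ~10-fold).

## The functional-unit model

The model encodes three energetic motifs inferred from the add-back
panels, as a log10-linear function of presence indicators:

$$\log_{10} k = \beta_0 + \sum_i \beta_i x_i
 + x_{166}(x_{101}\,\alpha_{101} + x_{153}\,\alpha_{153})
 + x_{322}\,x_{153}\,x_{328}\,\gamma
 + (x_{101} \lor x_{322})\,\rho$$

* **D101/R166/D153**: the arginine's contribution is boosted nearly
  additively (in free energy) by each flanking aspartate — hence two
  separate boosts α gated on R166's presence, not a three-way term.
* **D153/Mg²⁺/K328**: the Mg²⁺ contribution is enhanced ~100-fold only
  when D153 *and* K328 are both present — a single cooperative term γ
  gated on all three.
* **D101/Mg²⁺**: redundancy. Either group alone provides a ~20–30-fold
  advantage; having both adds nothing. The inclusive-OR indicator
  $x_{101} + x_{322} - x_{101}x_{322}$ grants ρ exactly once when at least
  one member is present, which is the algebraic form of "a benefit from
  each occurring only when the other is absent."

With the intercept this is ten parameters for 27 measured, non-censored
variants (26 mutants plus WT at its chemistry-limited value): the model is
overdetermined and, because every term is linear in the parameters, the
design matrix has full rank, making noiseless recovery exact.

### Fitting

Fitting is in log10 space. Two objectives:

* **least squares** (default): the estimation objective. When the censored
  record is not violated the solution is the closed-form linear solve,
  which is what makes exact noiseless parameter recovery (to < 10⁻⁶ log10
  units; in practice machine precision) testable.
* **minimax (Chebyshev)**: minimises the largest absolute log10 residual —
  the natural objective behind the claim that one model "accounts for every
  variant within a factor of x". It is solved by a convex log-sum-exp
  homotopy: minimise $f_k = k^{-1}\log\sum_i (e^{k r_i} + e^{-k r_i})$ with
  BFGS, warm-starting while the sharpness k increases through a fixed
  schedule (2 → 5000). Since $\max_i |r_i| \le f_k \le \max_i |r_i| +
  \log(2m)/k$, the final smoothing error is below 10⁻³ log10 units; the
  solution was additionally verified against an exact linear-programming
  solution of the same Chebyshev problem during development and agrees to
  7 decimal places.

Both objectives start from a deterministic initialisation (the closed-form
solution; no random restarts), so a fit is a pure function of its inputs.
The censored record contributes a one-sided penalty only when the model
predicts activity above its bound; in the fitted models it never does, so
the bound is reported but inactive.

On the packaged table the minimax fit attains a maximum fold deviation of
2.04 — a factor of two at the two-significant-figure precision of the
input data (the extreme residual sits on the D101A/E322Y arm). Dropping
the redundancy term (ρ ≡ 0) strictly degrades this maximum, which is the
quantitative case for the third functional unit. The least-squares fit
predicts the four never-expressed variants within 1.1–2.4-fold of the
model-derived values carried by the table; the tests bound this at a
factor of 2.5, reflecting that "about two-fold" at two-significant-figure
data precision cannot be held to exactly 2.0.

## Path accessibility

An edge is the addition of one residue (80 edges); a path is one of the
5! = 120 orderings of the five additions from the minimal enzyme to WT. A
step counts as selectively advantageous when its activity ratio is
**strictly** greater than the fold threshold (ratio = threshold never
passes); thresholds of 3 and 5 are the conventional cutoffs. Counting is
done two independent ways — exhaustive enumeration of the 120 orderings
and a dynamic program accumulating counts along passing edges — which must
agree exactly and are property-tested against each other on random
landscapes.

Counts at a 3-fold cutoff are intrinsically fragile: several edges have
ratios of 3.1–3.6 from inputs printed to two significant figures, so a
±1–2 path swing is within data precision. The shipped table gives 35
accessible orderings at >3-fold (either WT convention) and 62 of 80
passing edges; `accessibility_report()` therefore always lists the edges
within ±20% of the cutoff (at 3-fold this includes the final D101A → WT
step, ratio ≈ 3.3) so that any count is read together with its
sensitivity. Reported counts for this landscape of around 34 accessible
orderings are consistent with ours at that precision; smaller published
step tallies (e.g. 36 favourable edges) are not reproduced by a strict
>3-fold evaluation of all 80 printed-value edges under either WT
convention, and no counting rule we consider defensible yields them, so
the package reports its own exhaustively derived counts.

## Waiting-time models

States count acquired residues, 0..n, absorbing at n. Per-position
mutation rate is 1 (arbitrary time units throughout); an open position
acquires the advantageous residue with probability p = 1/20 (one residue
of twenty), and in the cooperative regime an acquired residue drifts away
with probability 1 − p. This gives:

* **cooperative**: λ~k~ = (n−k)p, μ~k~ = k(1−p). No selection until all n
  residues are simultaneously present. MFPT for n = 5, p = 1/20:
  6.8 × 10⁵.
* **stepwise**: λ~k~ = (n−k)p, μ = 0 (every step fixes). MFPT 45.7.
* **single pathway**: n irreversible steps at rate p. MFPT n/p = 100.

"Mean waiting time" follows the half-time convention, ln 2 × MFPT (69 and
32 for the single-path and stepwise extremes; 4.7 × 10⁵ cooperative), by
analogy with a first-order reaction's half-time; the raw MFPT is always
reported alongside. MFPTs are computed both by the standard birth–death
summation
$T = \sum_{k=0}^{n-1}\sum_{i=0}^{k} \lambda_i^{-1} \prod_{j=i+1}^{k} \mu_j/\lambda_j$
and by the first-step linear system; the two must agree to 10⁻¹⁰ relative
tolerance. A kinetic Monte Carlo simulator (`simulate_chain()`) provides a
stochastic oracle: its mean must fall within three standard errors of the
deterministic value. Simulation checks use the stepwise chain and a small
cooperative chain (n = 3, p = 1/4); the full cooperative chain needs
~7 × 10⁵ jump events per trajectory (absorption takes ~6.8 × 10⁵ time
units at order-one total rates), so it is validated by the two exact
methods against each other rather than by direct simulation.

`mfpt_general()` puts rates on the landscape itself: each passing edge is
an irreversible transition at rate p = 1/20 (a documented convention — the
per-edge rate is not pinned down by anything beyond the requirement that
the single-path and all-paths limits be recovered). Transitions are
restricted to passing edges lying on at least one fully accessible
ordering — both endpoints forward-reachable from the minimal enzyme and
backward-reachable from WT through passing edges. Without that
restriction, trajectories could enter dead-end genotypes with no
advantageous continuation and the mean absorption time would be infinite;
restricting to productive trajectories matches the premise that paths
stalling short of WT carry negligible probability. At a >3-fold cutoff the
landscape chain's half-time is 41, strictly inside the single-path /
stepwise bracket [32, 69]. The limits are exact: if all 80 edges pass the
chain reduces to the stepwise model, and if exactly one ordering is
accessible it reduces to the single-pathway model.

## Synthetic landscapes

`generate_landscape()` draws activities as
$10^{\mu_g + \bar\varepsilon}$ with μ~g~ the unit-model prediction and ε
i.i.d. Normal(0, σ) per replicate in log10 — log-normal noise, the natural
model for fold-type measurement error in rate constants. Defaults encode
the study conditions: σ = 0.15 log10 units (independent enzyme
preparations agreeing within two-fold corresponds to ~0.3 log10 units
between duplicates, i.e. a per-measurement σ of ~0.15), two replicates
averaged in log space (the geometric-mean convention), all 2⁵ genotypes
measured, and an optional censoring floor that turns low-activity variants
into upper-limit records. Seeds are mandatory and the global RNG state is
restored on exit, so generation is reproducible and side-effect free.

What the generator emulates: the multiplicative unit structure, the noise
scale, completeness, and censoring. What it does not: k~M~/k~cat~
decomposition, systematic (non-log-normal) assay error, any deviation from
the assumed unit algebra, and real structural idiosyncrasy of mutations.
Passing recovery tests therefore demonstrates that the estimator is
correct *under the model*, not that the model is true of any particular
enzyme.

`recovery_experiment()` fits each simulated landscape and summarises
per-parameter bias, its Monte-Carlo standard error, and RMSE. The
acceptance-level experiment uses 100 landscapes at σ = 0.15 — enough to
hold the bias of every parameter within three Monte-Carlo standard errors
of zero while keeping the whole suite fast — and noiseless recovery is
required to be exact to 10⁻⁶ log10 units.

## Numerical choices and degenerate inputs

* Canonical output formatting is two-significant-figure scientific
  notation, matching the precision of the source data; a load/write cycle
  is byte-idempotent.
* Equality-sensitive comparisons (strict edge thresholds) are plain
  floating-point comparisons on ratios of stored values; tests of
  strictness use activities that are exact powers of two so the ratios are
  exact.
* Oracle equivalences use 10⁻¹⁰ relative tolerance on chains with
  moderate rate heterogeneity (log-normal, σ~log~ = 1); with extreme rate
  ratios the MFPT magnitudes (≫10⁷) leave fewer than ten significant
  digits shared between any two double-precision algorithms, which is a
  conditioning limit, not an algorithmic disagreement.
* `fit_units()` errors on solver non-convergence rather than returning a
  partial answer; `mfpt_general()` errors when WT is unreachable through
  passing edges (e.g. thresholds above every edge ratio).
* Degenerate landscapes (missing or duplicate genotypes, non-positive
  activities, unknown aliases, repeated positions in a variant name) are
  rejected at load with row-level messages.

## Known limitations

* The unit algebra is fixed; the package does not search over alternative
  unit partitions, and a different interaction structure would require a
  different design matrix.
* Standard errors of measured activities are carried but not propagated
  through ratios or fits; derived quantities are point values read at
  two-significant-figure precision.
* The evolutionary models are residue-acquisition chains with a binary
  advantage cutoff — no population-genetic fixation probabilities,
  population sizes, or mutation biases.
* Everything is specific to the five-position, two-state landscape; n ≠ 5
  is rejected rather than approximated.
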