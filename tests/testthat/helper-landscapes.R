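# Shared fixtures, all built in code.

table1 <- builtin_table1()

# interaction-free (purely multiplicative) parameters
additive_params <- function(beta0 = -0.5,
                            betas = c(0.8, 1.6, -0.4, 2.2, 0.9)) {
  unit_params(beta0 = beta0, beta_101 = betas[1], beta_166 = betas[2],
              beta_153 = betas[3], beta_322 = betas[4], beta_328 = betas[5])
}

# random full parameter vector, reproducible
random_params <- function(seed) {
  set.seed(seed)
  p <- stats::rnorm(10, sd = 1)
  unit_params(beta0 = p[1], beta_101 = p[2], beta_166 = p[3],
              beta_153 = p[4], beta_322 = p[5], beta_328 = p[6],
              alpha_101 = p[7], alpha_153 = p[8], gamma = p[9], rho = p[10])
}

# landscape whose every residue exactly doubles activity (exact in binary
# floating point, so edge ratios are exactly 2)
doubling_landscape <- function() {
  g <- all_genotypes()
  n <- vapply(strsplit(g, ""), function(x) sum(x == "1"), integer(1))
  new_landscape(data.frame(genotype = g, kcat_km = 2^n,
                           stringsAsFactors = FALSE))
}

# landscape in which exactly one addition order is selectively accessible
single_path_landscape <- function(order = ap_residues()) {
  g <- all_genotypes()
  prefixes <- Reduce(function(b, r) apsite:::.genotype_with(b, r, TRUE),
                     order, "00000", accumulate = TRUE)
  act <- rep(1e-6, length(g))
  names(act) <- g
  act[prefixes] <- 10^(seq_along(prefixes) - 1)
  new_landscape(data.frame(genotype = g, kcat_km = unname(act[g]),
                           stringsAsFactors = FALSE))
}

# brute-force census used as the oracle against count_paths_dp
brute_force_path_count <- function(landscape, threshold, wt_convention = NULL) {
  act <- function(g) landscape_activity(landscape, g, wt_convention)
  count <- 0L
  for (perm in apsite:::.permutations(5L)) {
    g <- "00000"
    ok <- TRUE
    for (i in perm) {
      nxt <- apsite:::.genotype_with(g, ap_residues()[i], TRUE)
      if (!(act(nxt) / act(g) > threshold)) { ok <- FALSE; break }
      g <- nxt
    }
    if (ok) count <- count + 1L
  }
  count
}
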