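test_that("chain constructors produce the documented rates and reject bad input", {
  ch <- cooperative_chain(5, 1 / 20)
  expect_equal(ch$forward, c(0.25, 0.20, 0.15, 0.10, 0.05))
  expect_equal(ch$backward, c(0, 0.95, 1.90, 2.85, 3.80))
  expect_equal(ch$absorbing_state, 5L)
  expect_error(cooperative_chain(5, 0), "between 0 and 1")
  expect_error(cooperative_chain(5, 1), "between 0 and 1")
  expect_error(birth_death_chain(c(1, -1, 1)), "positive")
  expect_error(birth_death_chain(c(1, 1), backward = c(0.5, 0)), "mu_0")
  # p -> 1 reduces the cooperative chain to the stepwise chain
  near1 <- cooperative_chain(5, 1 - 1e-12)
  expect_equal(near1$backward, (0:4) * 1e-12, tolerance = 1e-6)
})

test_that("closed-form and linear-solve MFPTs agree to 1e-10 on random chains", {
  set.seed(99)
  for (i in 1:50) {
    n <- sample(2:8, 1)
    lam <- stats::rlnorm(n, sdlog = 1)
    mu <- c(0, stats::rlnorm(n - 1, sdlog = 1))
    ch <- birth_death_chain(lam, mu)
    tc <- mfpt_birth_death(ch, "closed_form")$mfpt
    tl <- mfpt_birth_death(ch, "linear_solve")$mfpt
    expect_equal(tc, tl, tolerance = 1e-10)
    expect_equal(mfpt_birth_death(ch, "both")$mfpt, tc, tolerance = 1e-10)
  }
})

test_that("forward-only chains reduce to the sum of exponential waits", {
  set.seed(7)
  lam <- stats::rlnorm(6)
  expect_equal(mfpt_birth_death(birth_death_chain(lam))$mfpt, sum(1 / lam),
               tolerance = 1e-12)
  # single-step chain: mean wait 1/lambda
  expect_equal(mfpt_birth_death(cooperative_chain(1, 1 / 20))$mfpt, 20)
  expect_equal(single_path_time(1, 1 / 20)$mfpt,
               mfpt_birth_death(cooperative_chain(1, 1 / 20))$mfpt)
  expect_equal(single_path_time(5, 1)$mfpt, 5)
})

test_that("the three evolutionary models reproduce the published waiting times", {
  coop <- mfpt_birth_death(cooperative_chain(5, 1 / 20), "both")
  expect_equal(signif(coop$mfpt, 2), 6.8e5)
  expect_equal(signif(coop$half_time, 2), 4.7e5)
  step <- mfpt_birth_death(stepwise_chain(5, 1 / 20), "both")
  expect_equal(step$mfpt, 20 * sum(1 / (5:1)), tolerance = 1e-12)
  expect_equal(signif(step$half_time, 2), 32)
  single <- single_path_time(5, 1 / 20)
  expect_equal(single$mfpt, 100)
  expect_equal(signif(single$half_time, 2), 69)
  # half-time is exactly ln 2 x MFPT
  expect_identical(coop$half_time, log(2) * coop$mfpt)
})

test_that("MFPT is monotone in the rates", {
  base <- birth_death_chain(c(1, 1, 1), c(0, 0.5, 0.5))
  t0 <- mfpt_birth_death(base)$mfpt
  slower <- birth_death_chain(c(1, 0.5, 1), c(0, 0.5, 0.5))
  expect_gt(mfpt_birth_death(slower)$mfpt, t0)
  leakier <- birth_death_chain(c(1, 1, 1), c(0, 0.5, 1.5))
  expect_gt(mfpt_birth_death(leakier)$mfpt, t0)
  faster <- birth_death_chain(c(2, 1, 1), c(0, 0.5, 0.5))
  expect_lt(mfpt_birth_death(faster)$mfpt, t0)
})

test_that("kinetic Monte Carlo agrees with the deterministic solvers", {
  step <- stepwise_chain(5, 1 / 20)
  sim <- simulate_chain(step, 2000, seed = 101)
  expect_lt(abs(sim$mfpt - 20 * sum(1 / (5:1))), 3 * sim$se)
  coop <- cooperative_chain(3, 1 / 4)
  sim2 <- simulate_chain(coop, 2000, seed = 202)
  expect_lt(abs(sim2$mfpt - mfpt_birth_death(coop, "linear_solve")$mfpt),
            3 * sim2$se)
  # determinism under a fixed seed; an explicit seed is mandatory
  expect_identical(simulate_chain(step, 50, seed = 3),
                   simulate_chain(step, 50, seed = 3))
  expect_error(simulate_chain(step, 10), "seed")
})

test_that("the landscape chain brackets the stepwise and single-path extremes", {
  # all 80 edges passing: identical to the stepwise chain, half-time ~32
  dbl <- doubling_landscape()
  all_edges <- mfpt_general(dbl, threshold = 1.5)
  expect_equal(all_edges$mfpt, 20 * sum(1 / (5:1)), tolerance = 1e-12)
  # exactly one accessible ordering: the single-path model, half-time ~69
  one <- mfpt_general(single_path_landscape(), threshold = 3)
  expect_equal(one$mfpt, 100, tolerance = 1e-12)
  # the real landscape at >3-fold lies strictly between the extremes
  mid <- mfpt_general(table1, threshold = 3)
  expect_gt(mid$half_time, 32)
  expect_lt(mid$half_time, 69)
  # unreachable absorbing state is an error
  expect_error(mfpt_general(dbl, threshold = 10), "not reachable")
})
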