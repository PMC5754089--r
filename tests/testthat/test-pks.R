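test_that("lambda is the mean of the pooled counts", {
  expect_equal(estimate_lambda(c(5L, 6L, 7L)), 6)
  expect_equal(estimate_lambda(c(0L, 0L, 0L)), 0)
  expect_error(estimate_lambda(integer(0)), "empty")
})

test_that("the PKS statistic equals the brute-force supremum", {
  expect_equal(pks_statistic(c(0L, 0L, 0L), 0), 0)
  d <- pks_statistic(0:9, 4.5)
  ecd <- vapply(0:50, function(k) mean(0:9 <= k), numeric(1))
  expect_equal(d, max(abs(ecd - ppois(0:50, 4.5))), tolerance = 1e-12)
  # invariant under permutation of the sample
  set.seed(5)
  x <- rpois(80, 7)
  expect_equal(pks_statistic(x, mean(x)), pks_statistic(sample(x), mean(x)))
})

test_that("tau selection matches an exhaustive scan oracle", {
  cfg <- synth_config(n_taxa = 5, n_trees = 25, seed = 61,
                      branch_model = list(kind = "poisson", lambda = 6))
  ens <- simulate_clock_ensemble(cfg)
  sel <- select_tree_count(ens, 1000)

  scan <- vapply(5:25, function(tau) {
    disc <- discretize(pooled_branch_lengths(ens, tau), 1000)
    pks_statistic(disc, estimate_lambda(disc))
  }, numeric(1))
  expect_equal(sel$tau, (5:25)[which.min(scan)])
  expect_equal(sel$d_at_tau, min(scan), tolerance = 1e-12)
  expect_error(select_tree_count(apply_burnin(ens, 0.9), 1000), "smaller")
})

test_that("tau selection breaks ties toward the smallest tau", {
  # identical trees: D is constant in tau, so the smallest admissible tau wins
  ens <- toy_ensemble(rep("((A:0.006,B:0.006):0.006,C:0.006);", 10))
  sel <- select_tree_count(ens, 1000)
  expect_equal(sel$tau, 3L)
})

test_that("bootstrap critical values shrink with n and vanish at lambda 0", {
  c30 <- pks_critical_value(6, 30, alpha = 0.05, reps = 2000, seed = 1)
  c300 <- pks_critical_value(6, 300, alpha = 0.05, reps = 2000, seed = 1)
  expect_gt(c30, c300)
  expect_equal(pks_critical_value(0, 50, reps = 2000), 0)
  expect_error(pks_critical_value(6, 30, reps = 10), "1000")
})

test_that("bootstrap p-values obey the quantile duality and edge cases", {
  reps <- 4000
  expect_equal(pks_p_value(0, 6, 50, reps = reps, seed = 2), 1)
  expect_equal(pks_p_value(1, 6, 50, reps = reps, seed = 2), 1 / (reps + 1))
  # p at the (1 - alpha) bootstrap quantile is about alpha (same seed)
  alpha <- 0.05
  crit <- pks_critical_value(6, 50, alpha = alpha, reps = reps, seed = 3)
  p <- pks_p_value(crit, 6, 50, reps = reps, seed = 3)
  expect_equal(p, alpha, tolerance = 0.02)
})

test_that("the DKW power bound behaves as stated", {
  expect_equal(power_lower_bound(0.1, 0.05, 100), 0)
  expect_equal(power_lower_bound(0.1, 0.1, 100), 0)
  b <- power_lower_bound(0.1, 0.3, 343)
  expect_equal(b, 1 - 2 * exp(-2 * 343 * 0.04), tolerance = 1e-12)
  expect_gte(b, 0.99)
  # non-decreasing in n and in delta
  expect_lte(power_lower_bound(0.1, 0.3, 100), power_lower_bound(0.1, 0.3, 200))
  expect_lte(power_lower_bound(0.1, 0.2, 200), power_lower_bound(0.1, 0.3, 200))
})

test_that("the full PKS run is deterministic and internally consistent", {
  cfg <- synth_config(n_taxa = 6, n_trees = 40, seed = 8, rho = 0.3,
                      branch_model = list(kind = "poisson", lambda = 6))
  ens <- simulate_clock_ensemble(cfg)
  r1 <- run_pks_test(ens, 1000, alpha = 0.01, burnin = 0.25, reps = 1500,
                     seed = 99)
  r2 <- run_pks_test(ens, 1000, alpha = 0.01, burnin = 0.25, reps = 1500,
                     seed = 99)
  expect_identical(r1, r2)
  expect_lte(r1$n_adjusted, r1$n_unadjusted)
  expect_equal(r1$n_unadjusted, r1$tau * r1$branches_per_tree)
  expect_identical(r1$reject, r1$d_pks > r1$d_critical)
  expect_gte(r1$p_value, 0)
  expect_lte(r1$p_value, 1)
})

test_that("an ESS override replaces the trace-estimated coefficient", {
  cfg <- synth_config(n_taxa = 6, n_trees = 40, seed = 9,
                      branch_model = list(kind = "poisson", lambda = 6))
  ens <- simulate_clock_ensemble(cfg)
  r <- run_pks_test(ens, 1000, burnin = 0, reps = 1500, seed = 1,
                    ess_override = 20)
  expect_equal(r$k, 0.5)
  expect_equal(r$n_adjusted, round(0.5 * r$n_unadjusted))
})

test_that("a mixture ensemble is rejected while its ingroup is not", {
  # two long edges among fifteen: the pooled counts are bimodal
  cfg <- synth_config(n_taxa = 9, n_trees = 80, seed = 12,
                      branch_model = list(kind = "mixture", lambda = c(6, 30)))
  ens <- simulate_mixture_ensemble(cfg, long_edges = c(1, 2))
  r <- run_pks_test(ens, 1000, alpha = 0.01, burnin = 0.25, reps = 1500,
                    seed = 4)
  expect_true(r$reject)
  # same ensemble against the correct mixture model: much smaller distance
  disc <- discretize(pooled_branch_lengths(apply_burnin(ens, 0.25), r$tau), 1000)
  mix <- poisson_mixture(c(6, 30), c(13 / 15, 2 / 15))
  expect_lt(sup_distance(step_ecdf(disc$counts), mix), r$d_pks)
})
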