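test_that("minimum-spectra filter retains max-count >= threshold", {
  counts <- rbind(a = c(0, 4, 1), b = c(3, 3, 3), c = c(10, 0, 0))
  expect_equal(unname(min_spectra_filter(counts)), c(TRUE, FALSE, TRUE))

  set.seed(61)
  m <- matrix(rpois(500 * 6, 2), 500, 6)
  expect_equal(min_spectra_filter(m, 4),
               apply(m, 1, function(k) max(k) >= 4))
})

test_that("beta-binomial likelihood converges to binomial as theta -> 0", {
  k <- c(3, 7, 12, 0)
  t <- c(100, 120, 150, 80)
  ll_bb <- hepaquant:::betabinom_loglik(k, t, 0.05, 1e-8)
  ll_bin <- sum(stats::dbinom(k, t, 0.05, log = TRUE))
  expect_lt(abs(ll_bb - ll_bin), 1e-4)
})

test_that("grouped beta-binomial test handles null-like and degenerate input", {
  # identical proportions across groups: no evidence
  expect_gt(beta_binomial_test(rep(20L, 6), rep(2000L, 6),
                               rep(1:3, each = 2)), 0.99)
  expect_equal(beta_binomial_test(rep(0L, 6), rep(2000L, 6),
                                  rep(1:3, each = 2)), 1)
  expect_error(beta_binomial_test(c(5, 5), c(10, 10), c(1, 1)), "two groups")
  expect_error(beta_binomial_test(c(11, 1), c(10, 10), c(1, 2)), "exceed")
})

test_that("grouped test maximum-likelihood matches the grid-search oracle", {
  # extreme two-group configuration: the free overdispersion under the null
  # absorbs part of the separation, capping the statistic near 16.4
  k <- c(0L, 0L, 50L, 50L)
  t <- rep(1000L, 4)
  orc <- oracle_bb_test(k, t, c(1, 1, 2, 2))
  p_impl <- beta_binomial_test(k, t, c(1, 1, 2, 2))
  expect_equal(p_impl, orc$p, tolerance = 1e-3)
  expect_lt(p_impl, 1e-3)

  set.seed(62)
  for (i in 1:8) {
    k <- rbetabinom(6, 500, runif(1, 0.005, 0.05), runif(1, 0.01, 0.2))
    t <- rep(500L, 6)
    g <- rep(1:2, each = 3)
    orc <- oracle_bb_test(k, t, g)
    expect_equal(beta_binomial_test(k, t, g), orc$p, tolerance = 1e-2)
  }
})

test_that("p-values are invariant to permuting samples within groups", {
  set.seed(63)
  k <- rbetabinom(12, 2000, 0.01, 0.05)
  t <- rep(2000L, 12)
  g <- rep(1:3, each = 4)
  p1 <- beta_binomial_test(k, t, g)
  perm <- c(sample(1:4), sample(5:8), sample(9:12))
  p2 <- beta_binomial_test(k[perm], t[perm], g)
  expect_equal(p1, p2, tolerance = 1e-8)
})

test_that("paired test is null on symmetric pairs, matches its oracle when extreme", {
  expect_gt(inverted_beta_binomial_test(c(10, 20, 30, 15), c(10, 20, 30, 15),
                                        rep(1000, 4), rep(1000, 4)), 0.99)
  expect_equal(inverted_beta_binomial_test(c(0L, 0L), c(0L, 0L),
                                           c(10, 10), c(10, 10)), 1)

  # one-sided extreme: all counts on one side of every pair. The null
  # absorbs this into boundary overdispersion, so the p-value is modest;
  # the implementation must match the grid-search oracle, and the evidence
  # must be far stronger than in the symmetric configuration
  ka <- c(0L, 0L, 0L, 0L); kb <- c(40L, 50L, 60L, 45L)
  orc <- oracle_ibb_test(ka, kb, rep(1000, 4), rep(1000, 4))
  p_impl <- inverted_beta_binomial_test(ka, kb, rep(1000, 4), rep(1000, 4))
  expect_equal(p_impl, orc$p, tolerance = 0.02)
  expect_lt(p_impl, 0.05)

  set.seed(64)
  for (i in 1:8) {
    s <- rnbinom(4, mu = 50, size = 5) + 1L
    ka <- rbinom(4, s, runif(1, 0.2, 0.8))
    orc <- oracle_ibb_test(ka, s - ka, rep(1000, 4), rep(1000, 4))
    p_i <- inverted_beta_binomial_test(ka, s - ka, rep(1000, 4), rep(1000, 4))
    expect_lt(abs(p_i - orc$p), 0.01)
  }
})

test_that("fold changes floor zero group means at the half-count limit", {
  g <- rep(1:2, each = 2)
  # absent group floored at 0.5 spectra / 100: 0.1 / 0.005 = 20
  expect_equal(max_pairwise_fc(c(0, 0, 10, 10), rep(100, 4), g), 20)
  expect_equal(max_pairwise_fc(c(0, 0, 0, 0), rep(100, 4), g), 1)
  expect_equal(max_pairwise_fc(c(5, 5, 10, 10), rep(100, 4), g), 2)
})

test_that("differential calls require both significance and fold change", {
  res <- call_differential(c(0.001, 0.001, 0.5), c(1.5, 3, 10))
  expect_equal(res$is_different, c(FALSE, TRUE, FALSE))
  expect_true(all(res$is_different ==
                    (res$holm_p < 0.05 & res$max_pairwise_fc > 2)))
})

test_that("batch stability pipeline finds planted effects without false calls", {
  cfg <- simulation_config(count_proteins = 300, seed = 65)
  sim <- simulate_counts(cfg, frac_differential = 0.05, planted_fc = 4)
  res <- batch_stability(sim$counts, sim$groups)
  truth <- sim$truth[rownames(sim$counts) %in% res$accession]
  # family-wise control keeps false calls essentially absent
  expect_lte(mean(res$is_different[!truth]), 0.05)
  # post-Holm sensitivity is count-limited at this depth; raw-test power
  # at alpha = 0.05 is high
  expect_gte(mean(res$raw_p[truth] < 0.05), 0.80)
  expect_gte(mean(res$is_different[truth]), 0.40)
})

test_that("constant depth and zero dispersion give Poisson-like counts", {
  cfg <- simulation_config(count_proteins = 400, count_dispersion = 0,
                           seed = 66)
  sim <- simulate_counts(cfg, depth_jitter = 0)
  expect_true(all(sim$counts >= 0))
  ratio <- apply(sim$counts, 1, var) / pmax(rowMeans(sim$counts), 1e-9)
  expect_gt(median(ratio), 0.8)
  expect_lt(median(ratio), 1.2)
})
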