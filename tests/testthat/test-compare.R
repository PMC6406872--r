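test_that("presence filter implements the >= 2-systems rule", {
  det <- rbind(c(TRUE, TRUE, TRUE),
               c(TRUE, FALSE, FALSE),
               c(TRUE, TRUE, FALSE))
  pf <- presence_filter(det)
  expect_equal(pf$retained, c(TRUE, FALSE, TRUE))
  expect_equal(pf$absent[3, ], c(FALSE, FALSE, TRUE))
  expect_false(any(pf$absent[2, ]))  # excluded proteins get no absence call

  # brute-force enumeration over random detection patterns
  set.seed(41)
  det <- matrix(runif(300) > 0.5, 100, 3)
  pf <- presence_filter(det)
  for (i in 1:100) {
    expect_equal(pf$retained[i], sum(det[i, ]) >= 2)
    if (pf$retained[i]) expect_equal(pf$absent[i, ], !det[i, ])
  }
})

test_that("ANOVA and Tukey behave on degenerate and strong-signal cases", {
  res <- anova_tukey(rep(3.2, 9), rep(1:3, each = 3))
  expect_equal(res$anova_p, 1)

  set.seed(42)
  vals <- c(rnorm(3, 0, 0.1), rnorm(3, 0, 0.1), rnorm(3, 10, 0.1))
  res <- anova_tukey(vals, rep(c("a", "b", "c"), each = 3))
  expect_lt(res$anova_p, 1e-6)
  expect_gt(res$tukey_p[["b-a"]], 0.05)
  expect_lt(res$tukey_p[["c-a"]], 1e-6)
  expect_lt(res$tukey_p[["c-b"]], 1e-6)

  # insufficient replication -> not comparable
  expect_null(anova_tukey(c(1, 2, 3), c("a", "a", "b")))
})

test_that("ANOVA p-values are uniform under the null", {
  set.seed(43)
  pv <- replicate(1000, anova_tukey(rnorm(9), rep(1:3, each = 3))$anova_p)
  expect_gt(stats::ks.test(pv, "punif")$p.value, 0.01)
})

test_that("ANOVA and Tukey match hand computations from sums of squares", {
  set.seed(44)
  for (i in 1:50) {
    n_i <- sample(2:5, 3, replace = TRUE)
    g <- rep(c("a", "b", "c"), n_i)
    v <- rnorm(sum(n_i)) + rep(rnorm(3, sd = 2), n_i)
    res <- anova_tukey(v, g)
    expect_equal(res$anova_p, oracle_anova_p(v, g), tolerance = 1e-6)
    orc <- oracle_tukey(v, g)
    expect_equal(res$tukey_p[names(orc)], orc, tolerance = 1e-6)
  }
})

test_that("Holm adjustment matches its step-down definition", {
  expect_equal(holm_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.04, 0.04))
  expect_equal(holm_adjust(1), 1)
  expect_error(holm_adjust(c(0.5, 1.2)), "0, 1")

  set.seed(45)
  for (i in 1:1000) {
    p <- runif(sample(1:20, 1))
    adj <- holm_adjust(p)
    expect_equal(adj, oracle_holm(p), tolerance = 1e-12)
    expect_true(all(adj >= p))
    expect_true(all(adj <= 1))
  }
})

test_that("categorization follows the fixed precedence", {
  expect_equal(categorize(NA, NA, TRUE, FALSE), "absent_present")
  expect_equal(categorize(25, 0.2, TRUE, TRUE), "obvious")
  expect_equal(categorize(1 / 25, 0.2, TRUE, TRUE), "obvious")  # both directions
  expect_equal(categorize(3, 0.01, TRUE, TRUE), "significant")
  expect_equal(categorize(1.1, 0.5, TRUE, TRUE), "unchanged")
  expect_equal(categorize(5, 0.01, TRUE, TRUE, comparable = FALSE),
               "not_comparable")
  # absent-present wins over any fold change
  expect_equal(categorize(100, 0.001, FALSE, TRUE), "absent_present")
  # fold change exactly at the threshold is not obvious (strict >)
  expect_equal(categorize(20, 0.5, TRUE, TRUE), "unchanged")
})

test_that("planted categories are recovered on synthetic three-system data", {
  # extreme planted effects must surface as an extreme call: fold-change
  # "obvious" or, when censoring hides one side entirely, absent-present
  for (noise in c(0, 0.2)) {
    cfg <- simulation_config(n_proteins = 1200, noise_sd = noise, seed = 46)
    pipe <- run_proteome_pipeline(cfg)
    cmp <- pipe$comparison
    tr <- pipe$sim$truth
    for (s in c("HepaRG", "HepG2")) {
      exp_cat <- tr$expected_category[, s]
      got <- cmp[[paste0("category_", s)]]
      planted_large <- exp_cat == "obvious" & cmp$retained
      recovery <- mean(got[planted_large] %in% c("obvious", "absent_present"))
      expect_gte(recovery, 0.90)
      planted_absent <- exp_cat == "absent_present" & cmp$retained
      expect_gte(mean(got[planted_absent] == "absent_present"), 0.90)
    }
  }
})

test_that("without planted effects nearly all fold changes stay below 10x", {
  cfg <- simulation_config(
    n_proteins = 800, noise_sd = 0.2, fraction_absent = 0,
    fc_fractions = c(none = 1, moderate = 0, large = 0), seed = 47
  )
  pipe <- run_proteome_pipeline(cfg)
  fc <- pipe$comparison$log10_fc_HepG2
  expect_gt(mean(abs(fc) < 1, na.rm = TRUE), 0.99)
})
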