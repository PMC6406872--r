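make_secretome_quant <- function(intensity) {
  samples <- expand.grid(injection_rep = 1:3, depletion_rep = 1:3)
  samples$sample <- paste0("d", samples$depletion_rep, "i", samples$injection_rep)
  quant_matrix(
    intensity,
    proteins = data.frame(accession = rownames(intensity)),
    samples = samples
  )
}

test_that("retention demands a hit in every depletion replicate", {
  dep <- rep(1:3, each = 3)
  # one injection hit per depletion replicate -> retained
  grid1 <- matrix(FALSE, 1, 9)
  grid1[1, c(1, 5, 9)] <- TRUE
  expect_true(retention_filter(grid1, dep))
  # all injections of two depletion reps, none of the third -> dropped
  grid2 <- matrix(c(rep(TRUE, 6), rep(FALSE, 3)), 1)
  expect_false(retention_filter(grid2, dep))

  # brute-force predicate over random grids
  set.seed(51)
  grids <- matrix(runif(500 * 9) > 0.6, 500, 9)
  expect_equal(retention_filter(grids, dep), oracle_retention(grids, dep))
})

test_that("retention is monotone: adding an identification never drops a protein", {
  set.seed(52)
  dep <- rep(1:3, each = 3)
  grids <- matrix(runif(200 * 9) > 0.6, 200, 9)
  before <- retention_filter(grids, dep)
  grids2 <- grids
  flip <- cbind(sample(200, 200, replace = TRUE), sample(9, 200, replace = TRUE))
  grids2[flip] <- TRUE
  after <- retention_filter(grids2, dep)
  expect_true(all(after >= before))
})

test_that("secretion route classification follows the precedence", {
  expect_equal(classify_secreted(TRUE, FALSE, FALSE), "classical")
  expect_equal(classify_secreted(FALSE, TRUE, TRUE), "nonclassical")
  expect_equal(classify_secreted(FALSE, FALSE, TRUE),
               "annotated_extracellular_or_exosome")
  expect_equal(classify_secreted(FALSE, FALSE, FALSE), "not_secreted")
  expect_warning(cls <- classify_secreted(NA, NA, NA), "not secreted")
  expect_equal(cls, "not_secreted")
})

test_that("secretion rates match the hand arithmetic oracle", {
  intensity <- matrix(5e8, 2, 9, dimnames = list(c("A", "B"), NULL))
  q <- make_secretome_quant(intensity)
  exp <- secretome_experiment(q, seeded_cells = 5e5, secretion_days = 2,
                              protein_before_ug = 120, protein_after_ug = 100,
                              albumin_purity = 0.9)
  sr <- secretion_rates(exp)
  # two proteins sharing 100 ug over 2 days and 0.5e6 cells: 5e4 ng/day/1e6
  expect_equal(sr$secretion_rate, c(5e4, 5e4))

  # doubling the seeded cells halves every rate
  exp2 <- secretome_experiment(q, seeded_cells = 1e6, secretion_days = 2,
                               protein_before_ug = 120, protein_after_ug = 100,
                               albumin_purity = 0.9)
  expect_equal(secretion_rates(exp2)$secretion_rate,
               sr$secretion_rate / 2)
})

test_that("secreted mass closes over the depleted fraction", {
  set.seed(53)
  intensity <- matrix(10^runif(90, 5, 9), 10, 9,
                      dimnames = list(paste0("P", 1:10), NULL))
  q <- make_secretome_quant(intensity)
  exp <- secretome_experiment(q, seeded_cells = 4.8e5, secretion_days = 2,
                              protein_before_ug = 60, protein_after_ug = 45,
                              albumin_purity = 0.85)
  sr <- secretion_rates(exp)
  recovered_ng <- sum(sr$secretion_rate) * exp$secretion_days *
    exp$seeded_cells / 1e6
  expect_equal(recovered_ng, 45e3, tolerance = 1e-6)
})

test_that("albumin rate derives from depletion loss and band purity", {
  intensity <- matrix(1e8, 2, 9, dimnames = list(c("A", "B"), NULL))
  q <- make_secretome_quant(intensity)
  exp <- secretome_experiment(q, seeded_cells = 5e5, secretion_days = 2,
                              protein_before_ug = 200, protein_after_ug = 180,
                              albumin_purity = 0.9)
  expect_equal(albumin_rate(exp), 1.8e4)

  exp0 <- secretome_experiment(q, seeded_cells = 5e5, secretion_days = 2,
                               protein_before_ug = 180, protein_after_ug = 180,
                               albumin_purity = 1)
  expect_equal(albumin_rate(exp0), 0)

  expect_error(
    secretome_experiment(q, seeded_cells = 5e5, secretion_days = 2,
                         protein_before_ug = 100, protein_after_ug = 120,
                         albumin_purity = 0.9),
    "cannot exceed"
  )
  expect_error(
    secretome_experiment(q, seeded_cells = 5e5, secretion_days = 2,
                         protein_before_ug = 120, protein_after_ug = 100,
                         albumin_purity = 1.2),
    "purity"
  )
})

test_that("leakage verdict uses a strict threshold", {
  rates <- data.frame(accession = c("ALB", "GOT1"),
                      secretion_rate = c(1e5, 3))
  rep1 <- leakage_report(rates)
  expect_false(rep1$low_leakage)      # GOT1 exactly at 3 fails (strict <)
  rates$secretion_rate[2] <- 2.9
  expect_true(leakage_report(rates)$low_leakage)
  # all markers absent -> pass
  expect_true(leakage_report(data.frame(accession = "ALB",
                                        secretion_rate = 1))$low_leakage)
  rates2 <- data.frame(accession = "GOT1", secretion_rate = 10)
  expect_false(leakage_report(rates2)$low_leakage)
})

test_that("simulated secretomes round-trip: exact noiseless, <10% noisy", {
  cfg <- simulation_config(seed = 54)
  ss <- simulate_secretome(cfg, noise_sd = 0, detect = FALSE)
  sr <- secretion_rates(ss$experiment)
  expect_equal(sr$secretion_rate, unname(ss$truth$rate), tolerance = 1e-12)
  expect_equal(albumin_rate(ss$experiment), ss$truth$albumin_rate,
               tolerance = 1e-9)

  ssn <- simulate_secretome(cfg, noise_sd = 0.2, detect = TRUE)
  srn <- secretion_rates(ssn$experiment)
  truth <- ssn$truth$rate[srn$accession]
  rel_err <- abs(srn$secretion_rate - truth) / truth
  expect_lt(median(rel_err), 0.10)

  # rates span several orders of magnitude under defaults
  expect_gte(log10(max(sr$secretion_rate) / min(sr$secretion_rate)), 5)
})
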