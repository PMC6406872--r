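test_that("molecular weights are sums of average residue masses plus water", {
  expect_equal(compute_molecular_weight("G"), 75.0666, tolerance = 1e-7)
  expect_equal(compute_molecular_weight("GG"), 132.1179, tolerance = 1e-7)
  # case and whitespace insensitive
  expect_equal(compute_molecular_weight(" gG\n"), 132.1179, tolerance = 1e-7)
  expect_error(compute_molecular_weight(""), "empty")
  expect_error(compute_molecular_weight("GJG"), "unrecognized")
  expect_error(compute_molecular_weight("GXG"), "unrecognized")
  expect_warning(mw <- compute_molecular_weight("GXG", permissive = TRUE),
                 "110")
  expect_equal(mw, 2 * 57.0513 + 110 + 18.0153, tolerance = 1e-7)
})

test_that("spherical cell volume follows the closed form", {
  expect_equal(cell_volume(1), 4 / 3 * pi)
  expect_equal(cell_volume(10), 4188.7902, tolerance = 1e-6)
  expect_error(cell_volume(0), "positive")
  expect_error(cell_volume(-2), "positive")
})

test_that("protein content per cell converts micrograms to pg/cell", {
  expect_equal(protein_per_cell(800, 4e6), 200)
  expect_equal(protein_per_cell(0, 1e6), 0)
  expect_equal(protein_per_cell(1, 1e3), 1000)
  expect_error(protein_per_cell(10, 0), "positive")
})

test_that("cell system profile derives volume and validates inputs", {
  prof <- cell_system_profile("HepaRG", 285, cell_radius_um = 8.1)
  expect_equal(prof$cell_volume_um3, 4 / 3 * pi * 8.1^3, tolerance = 1e-9)
  expect_error(cell_system_profile("X", 0), "positive")
})

test_that("TPA copy numbers match the hand mass-fraction oracle", {
  prof <- cell_system_profile("X", 300)
  res <- tpa_copy_numbers(c(A = 1e9, B = 1e9), prof, mw = c(5e4, 1e5))
  # each protein carries 150 pg; copies = 150e-12 * N_A / mw
  expect_equal(res$copies_per_cell,
               150e-12 * 6.02214076e23 / c(5e4, 1e5), tolerance = 1e-12)

  # a single detected protein carries the whole protein content
  res1 <- tpa_copy_numbers(c(A = 42), prof, mw = 6e4)
  expect_equal(res1$copies_per_cell, 300e-12 * 6.02214076e23 / 6e4)

  # equal intensities and masses split the content evenly
  n <- 7
  resn <- tpa_copy_numbers(rep(1e6, n), prof, mw = rep(5e4, n))
  expect_equal(resn$copies_per_cell,
               rep(300e-12 * 6.02214076e23 / (n * 5e4), n))

  expect_error(tpa_copy_numbers(c(A = NA_real_), prof, mw = 1e4), "missing")
})

test_that("copy numbers conserve mass and are scale invariant", {
  set.seed(21)
  for (rep in 1:5) {
    n <- 50
    intensity <- stats::setNames(10^runif(n, 4, 10), paste0("P", 1:n))
    intensity[sample(n, 5)] <- NA
    mw <- runif(n, 1e4, 3e5)
    prof <- cell_system_profile("S", runif(1, 100, 400))
    res <- tpa_copy_numbers(intensity, prof, mw = mw)
    tab <- copy_number_table(list(S = res), mw = mw)
    expect_lt(mass_conservation_error(tab), 1e-6)
    # scaling every intensity leaves copies unchanged
    res2 <- tpa_copy_numbers(intensity * 17.3, prof, mw = mw)
    expect_equal(res2$copies_per_cell, res$copies_per_cell, tolerance = 1e-12)
  }
})

test_that("copy numbers increase in intensity and decrease in mass", {
  prof <- cell_system_profile("S", 250)
  base <- tpa_copy_numbers(c(10, 20, 70), prof, mw = c(5e4, 5e4, 5e4))
  expect_true(all(diff(base$copies_per_cell) > 0))
  heavier <- tpa_copy_numbers(c(10, 20, 70), prof, mw = c(5e4, 8e4, 12e4))
  # same intensity, larger mass -> fewer copies
  expect_lt(heavier$copies_per_cell[2], base$copies_per_cell[2])
})

test_that("quant_matrix treats zero intensity as missing, not measured zero", {
  m <- matrix(c(0, 5, 3, 0), 2, 2)
  q <- quant_matrix(m,
                    proteins = data.frame(accession = c("A", "B")),
                    samples = data.frame(sample = c("s1", "s2")))
  expect_true(is.na(q$intensity[1, 1]))
  expect_true(is.na(q$intensity[2, 2]))
  expect_equal(q$intensity[2, 1], 5)
  expect_error(
    quant_matrix(matrix(-1, 1, 1),
                 proteins = data.frame(accession = "A"),
                 samples = data.frame(sample = "s")),
    "negative"
  )
})

test_that("replicate averaging ignores missing values per protein", {
  m <- matrix(c(2, NA, 4, NA, 6, NA), 2, 3)
  q <- quant_matrix(m,
                    proteins = data.frame(accession = c("A", "B")),
                    samples = data.frame(sample = paste0("s", 1:3),
                                         system = "S"))
  mi <- mean_intensity(q, "S")
  expect_equal(unname(mi), c(4, NA))
})
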