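#' Configuration for the synthetic-data generators
#'
#' Collects every knob of the simulators in one validated object. Defaults
#' emulate the structure of a deep hepatic label-free experiment: lognormal
#' copy numbers spanning well over five orders of magnitude, three cell
#' systems with a handful of replicates each, system-specific absent
#' proteins (rare in the reference, common in the least differentiated
#' line), a planted fold-change mixture (90% unchanged, 5% moderate 2-10x,
#' 5% large > 20x), multiplicative lognormal intensity noise, and
#' intensity-dependent missingness (left-censoring by a logistic detection
#' curve), which is exactly the feature that makes depth correction by
#' cyclic LOESS necessary. Counts follow a negative-binomial model over a
#' 3-batch x 4-replicate design; the secretome uses the 3 depletion x 3
#' injection grid.
#'
#' @param n_proteins Number of proteins.
#' @param systems Cell-system labels; first is the reference.
#' @param replicates Replicates per system (recycled).
#' @param log10_copy_mean,log10_copy_sd Lognormal copy-number distribution
#'   (log10 scale).
#' @param fraction_absent Per-system fraction of proteins truly absent
#'   (recycled over systems).
#' @param fc_fractions Named fractions of the fold-change mixture:
#'   none / moderate / large.
#' @param fc_moderate_range,fc_large_range Linear fold-change ranges for the
#'   two planted classes.
#' @param noise_sd Lognormal intensity noise (sd of the natural-log scale).
#' @param detect_midpoint,detect_scale Logistic detection curve on log10
#'   intensity: P(detect) = plogis((log10 I - midpoint) / scale).
#' @param n_batches,batch_replicates,count_proteins,count_depth,count_dispersion
#'   Spectral-count design: batches, replicates per batch, number of
#'   proteins, mean library size (MS/MS spectra per sample; the default
#'   pairs roughly 1200 testable proteins with a typical ion-trap yield of
#'   30000 spectra, so most proteins clear the 4-spectra filter), and
#'   negative-binomial dispersion (0 = Poisson).
#' @param secretome_proteins,log10_rate_mean,log10_rate_sd Secretome size
#'   and true secretion-rate distribution (log10 ng/day/1e6 cells).
#' @param seeded_cells,secretion_days,albumin_rate_true,albumin_purity
#'   Secretome experiment constants.
#' @param seed Mandatory RNG seed.
#' @return Object of class `sim_config`.
#' @export
simulation_config <- function(n_proteins = 5000L,
                              systems = c("PHH", "HepaRG", "HepG2"),
                              replicates = 3L,
                              log10_copy_mean = 4.5,
                              log10_copy_sd = 1.2,
                              fraction_absent = c(0.008, 0.02, 0.12),
                              fc_fractions = c(none = 0.90, moderate = 0.05,
                                               large = 0.05),
                              fc_moderate_range = c(2, 10),
                              fc_large_range = c(20, 1000),
                              noise_sd = 0.2,
                              detect_midpoint = 6.5,
                              detect_scale = 0.4,
                              n_batches = 3L,
                              batch_replicates = 4L,
                              count_proteins = 1200L,
                              count_depth = 30000L,
                              count_weight_sd = 0.3,
                              count_dispersion = 0.05,
                              secretome_proteins = 300L,
                              log10_rate_mean = 1.5,
                              log10_rate_sd = 1.3,
                              seeded_cells = 4.8e5,
                              secretion_days = 2,
                              albumin_rate_true = 2e4,
                              albumin_purity = 0.9,
                              seed) {
  if (missing(seed)) stop("a seed is mandatory for every simulation")
  stopifnot(n_proteins >= 2, length(systems) >= 1,
            all(fraction_absent >= 0 & fraction_absent <= 1),
            abs(sum(fc_fractions) - 1) < 1e-9,
            noise_sd >= 0, count_dispersion >= 0)
  cfg <- as.list(environment())
  cfg$replicates <- rep_len(replicates, length(systems))
  cfg$fraction_absent <- rep_len(fraction_absent, length(systems))
  structure(cfg, class = "sim_config")
}

#' Simulate a multi-system proteome with known ground truth
#'
#' Draws true copies per cell and molecular weights, plants per-system
#' absences and fold changes versus the reference system, generates raw
#' intensities I = copies x MW x exp(noise) per replicate, and censors low
#' intensities through the logistic detection curve. With zero noise and no
#' censoring the Total Protein Approach recovers the planted copy numbers
#' exactly, because intensity shares then equal mass shares.
#'
#' @param cfg A [simulation_config()].
#' @return List: `quant` (a `quant_matrix` over all system replicates),
#'   `profiles` (per-system [cell_system_profile()] consistent with the
#'   planted copies), `truth` (true copies matrix proteins x systems, planted
#'   fold-change class, per-system absence flags and expected categories).
#' @export
simulate_proteome <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n_proteins
  acc <- sprintf("SIM%05d", seq_len(n))
  mw <- pmin(pmax(stats::rlnorm(n, meanlog = log(4e4), sdlog = 0.5), 5e3), 1e6)
  base_copies <- 10^stats::rnorm(n, cfg$log10_copy_mean, cfg$log10_copy_sd)

  n_sys <- length(cfg$systems)
  fc_class <- sample(names(cfg$fc_fractions), n, replace = TRUE,
                     prob = cfg$fc_fractions)
  true_copies <- matrix(base_copies, n, n_sys,
                        dimnames = list(acc, cfg$systems))
  # planted effects apply to the non-reference systems, direction random
  for (j in seq_len(n_sys)[-1]) {
    fc <- rep(1, n)
    mod <- fc_class == "moderate"
    lrg <- fc_class == "large"
    fc[mod] <- stats::runif(sum(mod), cfg$fc_moderate_range[1L],
                            cfg$fc_moderate_range[2L])
    fc[lrg] <- stats::runif(sum(lrg), cfg$fc_large_range[1L],
                            cfg$fc_large_range[2L])
    up <- sample(c(TRUE, FALSE), n, replace = TRUE)
    fc[!up] <- 1 / fc[!up]
    true_copies[, j] <- base_copies * fc
  }
  absent <- vapply(seq_len(n_sys), function(j) {
    stats::runif(n) < cfg$fraction_absent[j]
  }, logical(n))
  dimnames(absent) <- list(acc, cfg$systems)
  true_copies[absent] <- 0

  sample_system <- rep(cfg$systems, times = cfg$replicates)
  sample_id <- unlist(lapply(seq_len(n_sys), function(j) {
    paste0(cfg$systems[j], "_r", seq_len(cfg$replicates[j]))
  }))
  intensity <- matrix(NA_real_, n, length(sample_id),
                      dimnames = list(acc, sample_id))
  for (col in seq_along(sample_id)) {
    j <- match(sample_system[col], cfg$systems)
    c_true <- true_copies[, j]
    noise <- if (cfg$noise_sd > 0) exp(stats::rnorm(n, 0, cfg$noise_sd)) else 1
    ival <- c_true * mw * noise
    detected <- ival > 0
    if (cfg$detect_scale > 0) {
      p_det <- stats::plogis((log10(pmax(ival, 1e-300)) - cfg$detect_midpoint) /
                               cfg$detect_scale)
      detected <- detected & (stats::runif(n) < p_det)
    }
    intensity[detected, col] <- ival[detected]
  }

  profiles <- lapply(seq_len(n_sys), function(j) {
    p_cell_pg <- sum(true_copies[, j] * mw) / AVOGADRO * 1e12
    cell_system_profile(cfg$systems[j], p_cell_pg)
  })
  names(profiles) <- cfg$systems

  expected_category <- vapply(seq_len(n_sys)[-1], function(j) {
    ifelse(xor(absent[, j], absent[, 1L]), "absent_present",
           ifelse(absent[, j] & absent[, 1L], "not_comparable",
                  ifelse(fc_class == "large", "obvious",
                         ifelse(fc_class == "moderate", "moderate", "none"))))
  }, character(n))
  colnames(expected_category) <- cfg$systems[-1L]

  list(
    quant = quant_matrix(
      intensity,
      proteins = data.frame(accession = acc, mw = mw),
      samples = data.frame(sample = sample_id, system = sample_system)
    ),
    profiles = profiles,
    truth = list(
      copies = true_copies,
      mw = mw,
      fc_class = fc_class,
      absent = absent,
      expected_category = expected_category
    )
  )
}

#' Draw beta-binomial counts
#'
#' @param n Number of draws.
#' @param size Totals (recycled).
#' @param pi_,theta Mean proportion and overdispersion; theta = 0 gives
#'   plain binomial draws.
#' @return Integer vector.
#' @export
rbetabinom <- function(n, size, pi_, theta) {
  size <- rep_len(size, n)
  if (theta <= 0) return(stats::rbinom(n, size, pi_))
  a <- pi_ * (1 - theta) / theta
  b <- (1 - pi_) * (1 - theta) / theta
  stats::rbinom(n, size, stats::rbeta(n, a, b))
}

#' Simulate a batch-design spectral-count matrix with known labels
#'
#' Protein baseline abundances follow the lognormal copy model; expected
#' counts are proportional to abundance times a per-sample library depth,
#' drawn negative-binomially (Poisson when dispersion is 0). A fraction of
#' proteins get a planted fold change in the last batch.
#'
#' @param cfg A [simulation_config()].
#' @param frac_differential Fraction of proteins with a planted batch
#'   effect, default 0.
#' @param planted_fc Fold change applied in the last batch, default 4.
#' @param depth_jitter Relative spread of per-sample library depth (uniform
#'   on 1 +/- depth_jitter); 0 gives constant depth.
#' @return List: `counts` matrix, `groups` batch labels, `truth` logical
#'   vector of planted proteins.
#' @export
simulate_counts <- function(cfg, frac_differential = 0, planted_fc = 4,
                            depth_jitter = 0.2) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 1L)
  n <- cfg$count_proteins
  acc <- sprintf("SIM%05d", seq_len(n))
  # abundance spread of the TESTED cohort: the >=4-spectra filter truncates
  # the full dynamic range, leaving a fairly homogeneous count regime
  weight <- 10^stats::rnorm(n, 0, cfg$count_weight_sd)
  groups <- rep(paste0("batch", seq_len(cfg$n_batches)),
                each = cfg$batch_replicates)
  n_samp <- length(groups)
  depth <- cfg$count_depth *
    stats::runif(n_samp, 1 - depth_jitter, 1 + depth_jitter)
  is_diff <- stats::runif(n) < frac_differential
  counts <- matrix(0L, n, n_samp, dimnames = list(
    acc, paste0(groups, "_r", sequence(rep(cfg$batch_replicates, cfg$n_batches)))
  ))
  last_batch <- groups == paste0("batch", cfg$n_batches)
  for (j in seq_len(n_samp)) {
    w <- weight
    if (last_batch[j]) w[is_diff] <- w[is_diff] * planted_fc
    mu <- w / sum(weight) * depth[j]
    counts[, j] <- if (cfg$count_dispersion > 0) {
      stats::rnbinom(n, mu = mu, size = 1 / cfg$count_dispersion)
    } else {
      stats::rpois(n, mu)
    }
  }
  list(counts = counts, groups = groups, truth = is_diff)
}

#' Simulate a secretome experiment with known secretion rates
#'
#' True secretion rates are lognormal (spanning several orders of
#' magnitude, like a hepatic secretome that runs from sub-nanogram growth
#' factors to microgram carrier proteins). Intensities over the 3 depletion
#' x 3 injection grid are proportional to each protein's secreted mass with
#' multiplicative noise; identification per grid cell follows the logistic
#' detection curve. Albumin is handled outside the intensity table: its
#' planted rate fixes the depletion loss via the bound-fraction purity.
#'
#' @param cfg A [simulation_config()].
#' @param noise_sd Override for the intensity noise sd (defaults to
#'   `cfg$noise_sd`).
#' @param detect Apply the logistic identification model? Default TRUE;
#'   FALSE identifies everything everywhere (noiseless round-trips).
#' @return List: `experiment` (a `secretome_experiment`), `truth` (true
#'   rates ng/day/1e6 cells, albumin rate, and the identification grid).
#' @export
simulate_secretome <- function(cfg, noise_sd = cfg$noise_sd, detect = TRUE) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 2L)
  n <- cfg$secretome_proteins
  acc <- sprintf("SEC%04d", seq_len(n))
  true_rate <- 10^stats::rnorm(n, cfg$log10_rate_mean, cfg$log10_rate_sd)
  denom <- cfg$secretion_days * cfg$seeded_cells / 1e6
  mass_ng <- true_rate * denom               # per-protein mass in the depleted fraction
  protein_after_ug <- sum(mass_ng) / 1e3
  albumin_mass_ng <- cfg$albumin_rate_true * denom
  loss_ug <- albumin_mass_ng / cfg$albumin_purity / 1e3
  protein_before_ug <- protein_after_ug + loss_ug

  samples <- expand.grid(injection_rep = 1:3, depletion_rep = 1:3)
  samples <- samples[, c("depletion_rep", "injection_rep")]
  samples$sample <- paste0("dep", samples$depletion_rep,
                           "_inj", samples$injection_rep)
  intensity <- matrix(NA_real_, n, nrow(samples),
                      dimnames = list(acc, samples$sample))
  for (j in seq_len(nrow(samples))) {
    noise <- if (noise_sd > 0) exp(stats::rnorm(n, 0, noise_sd)) else 1
    ival <- mass_ng * noise
    identified <- rep(TRUE, n)
    if (detect && cfg$detect_scale > 0) {
      p_det <- stats::plogis((log10(ival) - (cfg$log10_rate_mean - 2.5)) /
                               cfg$detect_scale)
      identified <- stats::runif(n) < p_det
    }
    intensity[identified, j] <- ival[identified]
  }
  q <- quant_matrix(
    intensity,
    proteins = data.frame(accession = acc,
                          mw = stats::rlnorm(n, log(5e4), 0.4)),
    samples = samples
  )
  exp <- secretome_experiment(
    q,
    seeded_cells = cfg$seeded_cells,
    secretion_days = cfg$secretion_days,
    protein_before_ug = protein_before_ug,
    protein_after_ug = protein_after_ug,
    albumin_purity = cfg$albumin_purity
  )
  list(
    experiment = exp,
    truth = list(
      rate = stats::setNames(true_rate, acc),
      albumin_rate = cfg$albumin_rate_true,
      identified = !is.na(intensity)
    )
  )
}
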