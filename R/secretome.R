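#' Secretome experiment description
#'
#' Bundles the measurements needed to turn depleted-secretome intensities
#' into absolute secretion rates: the replicate design (3 albumin-depletion
#' replicates x 3 LC-MS injection replicates), how many cells were seeded,
#' how long they secreted into the medium, the protein amounts before and
#' after immunodepletion, and the purity of the albumin band in the bound
#' fraction (from Coomassie gel densitometry).
#'
#' @param quant A `quant_matrix` whose samples carry `depletion_rep` and
#'   `injection_rep` columns (values 1..3 each).
#' @param seeded_cells Number of seeded cells per well.
#' @param secretion_days Days of secretion before medium collection
#'   (default 2).
#' @param protein_before_ug Protein amount before albumin depletion, ug.
#' @param protein_after_ug Protein amount after depletion, ug.
#' @param albumin_purity Fraction of the bound (depleted) material that is
#'   albumin, in (0, 1].
#' @return Object of class `secretome_experiment`.
#' @export
secretome_experiment <- function(quant, seeded_cells, secretion_days = 2,
                                 protein_before_ug, protein_after_ug,
                                 albumin_purity) {
  stopifnot(inherits(quant, "quant_matrix"))
  if (!all(c("depletion_rep", "injection_rep") %in% names(quant$samples))) {
    stop("secretome samples need 'depletion_rep' and 'injection_rep' columns")
  }
  if (seeded_cells <= 0) stop("seeded_cells must be positive")
  if (secretion_days <= 0) stop("secretion_days must be positive")
  if (protein_after_ug > protein_before_ug) {
    stop("protein after depletion cannot exceed protein before depletion")
  }
  if (albumin_purity <= 0 || albumin_purity > 1) {
    stop("albumin_purity must lie in (0, 1]")
  }
  structure(
    list(
      quant = quant,
      seeded_cells = seeded_cells,
      secretion_days = secretion_days,
      protein_before_ug = protein_before_ug,
      protein_after_ug = protein_after_ug,
      albumin_purity = albumin_purity
    ),
    class = "secretome_experiment"
  )
}

#' Secretome retention filter over the depletion x injection grid
#'
#' A protein is kept only if it was identified in at least one of the
#' injection replicates within every depletion replicate — identification
#' must be reproducible across the biochemical (depletion) replicates, while
#' one hit among the technical injections suffices. Missing grid cells count
#' as not identified.
#'
#' @param identified Logical matrix, proteins x samples (TRUE = identified),
#'   or a `quant_matrix` (identified = non-missing intensity).
#' @param depletion_rep Integer vector assigning samples to depletion
#'   replicates (taken from the sample table for a `quant_matrix`).
#' @return Logical vector: retained per protein.
#' @export
retention_filter <- function(identified, depletion_rep = NULL) {
  if (inherits(identified, "quant_matrix")) {
    depletion_rep <- identified$samples$depletion_rep
    identified <- !is.na(identified$intensity)
  }
  stopifnot(is.matrix(identified), is.logical(identified),
            length(depletion_rep) == ncol(identified))
  identified[is.na(identified)] <- FALSE
  reps <- unique(depletion_rep)
  hit_per_rep <- vapply(
    reps,
    function(r) rowSums(identified[, depletion_rep == r, drop = FALSE]) > 0,
    logical(nrow(identified))
  )
  # vapply drops to a vector for a single protein
  hit_per_rep <- matrix(hit_per_rep, nrow = nrow(identified),
                        dimnames = list(rownames(identified), NULL))
  rowSums(hit_per_rep) == length(reps)
}

#' Classify a protein's secretion route
#'
#' Bona-fide secreted proteins carry a signal peptide (classical secretory
#' pathway) or are predicted to leave the cell by non-classical routes; the
#' remaining proteins still count as secreted when annotated to the
#' extracellular space or to exosomes. Precedence: classical > nonclassical >
#' annotated extracellular/exosome > not secreted. The predictor outputs
#' (SignalP-style, SecretomeP-style) are consumed as precomputed flags, never
#' re-derived from sequence.
#'
#' @param signal_peptide,nonclassical,extracellular_or_exosome Logical
#'   vectors (recycled); NA rows are treated as not secreted with a warning.
#' @return Character vector with levels "classical", "nonclassical",
#'   "annotated_extracellular_or_exosome", "not_secreted".
#' @export
classify_secreted <- function(signal_peptide, nonclassical,
                              extracellular_or_exosome) {
  n <- max(length(signal_peptide), length(nonclassical),
           length(extracellular_or_exosome))
  sp <- rep_len(signal_peptide, n)
  nc <- rep_len(nonclassical, n)
  ex <- rep_len(extracellular_or_exosome, n)
  miss <- is.na(sp) & is.na(nc) & is.na(ex)
  if (any(miss)) {
    warning(sum(miss), " protein(s) without annotation treated as not secreted")
  }
  sp[is.na(sp)] <- FALSE; nc[is.na(nc)] <- FALSE; ex[is.na(ex)] <- FALSE
  ifelse(sp, "classical",
         ifelse(nc, "nonclassical",
                ifelse(ex, "annotated_extracellular_or_exosome",
                       "not_secreted")))
}

#' Absolute secretion rates by the Total Protein Approach
#'
#' Each retained protein's share of the summed mean intensity is taken as its
#' share of the total protein mass recovered in the albumin-depleted
#' supernatant; that mass is then normalized to the number of seeded cells
#' and the days of secretion:
#' \deqn{rate_i = \frac{I_i}{\sum_j I_j} \cdot
#'   \frac{P_{depleted}\,[\mathrm{ng}]}{D \cdot N_{seeded}/10^6}}
#' in ng/day/10^6 cells. Replicate intensities are averaged (non-missing)
#' first.
#'
#' @param exp A `secretome_experiment`.
#' @param retained Optional logical vector of retained proteins; defaults to
#'   [retention_filter()] on the experiment's grid.
#' @param total Which protein mass the intensity shares are scaled to:
#'   `"depleted"` (default) uses the protein amount measured after albumin
#'   depletion — the mass that was actually injected and generated the
#'   intensities; `"depleted_plus_albumin"` adds the purity-corrected
#'   albumin loss back, for the reading where shares refer to the whole
#'   secreted mass.
#' @return Data frame: `accession`, `mean_intensity`, `secretion_rate`
#'   (ng/day/1e6 cells) for retained proteins.
#' @export
secretion_rates <- function(exp, retained = NULL,
                            total = c("depleted", "depleted_plus_albumin")) {
  stopifnot(inherits(exp, "secretome_experiment"))
  total <- match.arg(total)
  if (is.null(retained)) retained <- retention_filter(exp$quant)
  intensity <- mean_intensity(exp$quant)[retained]
  if (all(is.na(intensity)) || sum(intensity, na.rm = TRUE) <= 0) {
    stop("summed intensity of retained proteins is zero")
  }
  share <- intensity / sum(intensity, na.rm = TRUE)
  total_ng <- exp$protein_after_ug * 1e3
  if (total == "depleted_plus_albumin") {
    total_ng <- total_ng +
      (exp$protein_before_ug - exp$protein_after_ug) * exp$albumin_purity * 1e3
  }
  denom <- exp$secretion_days * exp$seeded_cells / 1e6
  data.frame(
    accession = exp$quant$proteins$accession[retained],
    mean_intensity = intensity,
    secretion_rate = share * total_ng / denom,
    row.names = NULL
  )
}

#' Albumin secretion rate from immunodepletion loss
#'
#' Albumin is removed by immunodepletion before LC-MS, so its rate cannot
#' come from intensities. Instead the protein mass lost during depletion,
#' corrected by the measured purity of the albumin band in the bound
#' fraction, estimates the secreted albumin mass, normalized like every
#' other rate.
#'
#' @param exp A `secretome_experiment`.
#' @return Albumin secretion rate, ng/day/1e6 cells.
#' @export
albumin_rate <- function(exp) {
  stopifnot(inherits(exp, "secretome_experiment"))
  loss_ng <- (exp$protein_before_ug - exp$protein_after_ug) * 1e3
  loss_ng * exp$albumin_purity /
    (exp$secretion_days * exp$seeded_cells / 1e6)
}

#' Cell-leakage marker report
#'
#' Intracellular enzymes (lactate dehydrogenase, aspartate and alanine
#' aminotransferases) appear in the medium only through cell death; their
#' secretion rates gauge how much of the secretome is leakage. The verdict
#' passes when every detected marker stays strictly below the threshold.
#'
#' @param rates A [secretion_rates()] data frame.
#' @param markers Accessions (or gene symbols matching the accession column)
#'   of the leakage markers. Default: LDHA, LDHB, GOT1, GPT.
#' @param threshold Rate threshold, ng/day/1e6 cells (default 3; a marker at
#'   or above the threshold fails).
#' @return List with `table` (marker, rate, below_threshold) and `low_leakage`
#'   verdict.
#' @export
leakage_report <- function(rates, markers = c("LDHA", "LDHB", "GOT1", "GPT"),
                           threshold = 3) {
  idx <- match(markers, rates$accession)
  rate <- rates$secretion_rate[idx]
  tab <- data.frame(
    marker = markers,
    secretion_rate = rate,
    below_threshold = is.na(rate) | rate < threshold
  )
  list(table = tab, low_leakage = all(tab$below_threshold))
}
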