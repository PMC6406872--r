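#' Cell volume from radius assuming a spherical cell
#'
#' Cells measured in suspension are close to spherical, so the average radius
#' gives the volume directly.
#'
#' @param radius Cell radius in micrometres; must be positive.
#' @return Volume in cubic micrometres, (4/3) * pi * r^3.
#' @export
cell_volume <- function(radius) {
  stopifnot(is.numeric(radius))
  if (any(!is.finite(radius)) || any(radius <= 0)) {
    stop("cell radius must be positive and finite")
  }
  (4 / 3) * pi * radius^3
}

#' Protein content per cell
#'
#' Converts a bulk protein assay result (e.g. BCA on a lysed, counted cell
#' pellet) into picograms of protein per cell.
#'
#' @param total_protein_ug Total protein in the lysate, micrograms.
#' @param cell_count Number of cells lysed; must be positive.
#' @return Protein mass per cell in pg/cell.
#' @export
protein_per_cell <- function(total_protein_ug, cell_count) {
  stopifnot(is.numeric(total_protein_ug), is.numeric(cell_count))
  if (any(total_protein_ug < 0)) stop("total protein must be non-negative")
  if (any(cell_count <= 0)) stop("cell count must be positive")
  total_protein_ug * 1e6 / cell_count
}

#' Physical profile of a cell system
#'
#' Bundles the per-cell physical parameters the Total Protein Approach needs:
#' the measured total protein mass per cell and, optionally, the average cell
#' radius (from which the spherical volume is derived) and the number of
#' seeded cells (used for secretome rate normalization).
#'
#' @param system_name Label, e.g. "HepaRG", "PHH", "HepG2".
#' @param protein_per_cell_pg Total protein content, pg/cell; positive.
#' @param cell_radius_um Optional average cell radius, micrometres.
#' @param seeded_cells Optional number of seeded cells per well.
#' @return An object of class `cell_system_profile`.
#' @export
cell_system_profile <- function(system_name, protein_per_cell_pg,
                                cell_radius_um = NULL, seeded_cells = NULL) {
  stopifnot(is.character(system_name), length(system_name) == 1L)
  if (!is.numeric(protein_per_cell_pg) || protein_per_cell_pg <= 0) {
    stop("protein_per_cell_pg must be a positive number")
  }
  volume <- if (!is.null(cell_radius_um)) cell_volume(cell_radius_um) else NULL
  if (!is.null(seeded_cells) && seeded_cells <= 0) {
    stop("seeded_cells must be positive")
  }
  structure(
    list(
      system_name = system_name,
      protein_per_cell_pg = protein_per_cell_pg,
      cell_radius_um = cell_radius_um,
      cell_volume_um3 = volume,
      seeded_cells = seeded_cells
    ),
    class = "cell_system_profile"
  )
}

#' @export
print.cell_system_profile <- function(x, ...) {
  cat("Cell system profile:", x$system_name, "\n")
  cat("  protein per cell:", x$protein_per_cell_pg, "pg\n")
  if (!is.null(x$cell_radius_um)) {
    cat("  radius:", x$cell_radius_um, "um  volume:",
        format(x$cell_volume_um3, digits = 6), "um^3\n")
  }
  if (!is.null(x$seeded_cells)) cat("  seeded cells:", x$seeded_cells, "\n")
  invisible(x)
}

#' Protein intensity matrix with sample metadata
#'
#' Container for a label-free quantification experiment: a proteins x samples
#' matrix of raw intensities (NA = not detected; zero intensity in input files
#' is treated as missing, never as a measured zero), parallel protein
#' metadata (accession, molecular weight, flags) and sample metadata (cell
#' system, batch, replicate structure). An optional matrix of MS/MS spectral
#' counts may ride along.
#'
#' @param intensity Numeric matrix, proteins x samples; non-negative or NA.
#'   Row names are protein accessions, column names sample identifiers.
#' @param proteins Data frame with one row per protein; must contain
#'   `accession` and, for quantification, `mw` (g/mol).
#' @param samples Data frame with one row per sample; must contain `sample`
#'   and usually `system`; optional `batch`, `depletion_rep`, `injection_rep`.
#' @param msms_count Optional integer matrix of MS/MS counts, same dim.
#' @return An object of class `quant_matrix`.
#' @export
quant_matrix <- function(intensity, proteins, samples, msms_count = NULL) {
  stopifnot(is.matrix(intensity), is.data.frame(proteins), is.data.frame(samples))
  if (nrow(intensity) != nrow(proteins)) {
    stop("intensity rows must match protein table rows")
  }
  if (ncol(intensity) != nrow(samples)) {
    stop("intensity columns must match sample table rows")
  }
  if (!"accession" %in% names(proteins)) stop("proteins needs an 'accession' column")
  if (!"sample" %in% names(samples)) stop("samples needs a 'sample' column")
  if (anyDuplicated(proteins$accession)) stop("duplicate protein accessions")
  if (anyDuplicated(samples$sample)) stop("duplicate sample names")
  if (any(intensity < 0, na.rm = TRUE)) stop("negative intensities not allowed")
  # zero is the file convention for "not detected"
  intensity[!is.na(intensity) & intensity == 0] <- NA_real_
  rownames(intensity) <- proteins$accession
  colnames(intensity) <- samples$sample
  if (!is.null(msms_count)) {
    stopifnot(is.matrix(msms_count), all(dim(msms_count) == dim(intensity)))
    if (any(msms_count < 0, na.rm = TRUE)) stop("negative MS/MS counts not allowed")
    dimnames(msms_count) <- dimnames(intensity)
  }
  structure(
    list(
      intensity = intensity,
      proteins = proteins,
      samples = samples,
      msms_count = msms_count
    ),
    class = "quant_matrix"
  )
}

#' @export
print.quant_matrix <- function(x, ...) {
  cat("quant_matrix:", nrow(x$intensity), "proteins x",
      ncol(x$intensity), "samples\n")
  if ("system" %in% names(x$samples)) {
    cat("  systems:", paste(unique(x$samples$system), collapse = ", "), "\n")
  }
  cat("  detected entries:", sum(!is.na(x$intensity)), "of",
      length(x$intensity), "\n")
  invisible(x)
}

#' Average replicate intensities within one cell system
#'
#' Arithmetic mean of the non-missing raw intensities across a system's
#' replicate columns; a protein missing in every replicate stays missing.
#'
#' @param q A `quant_matrix`.
#' @param system Optional system label; defaults to all samples.
#' @return Named numeric vector of mean intensities (NA where never detected).
#' @export
mean_intensity <- function(q, system = NULL) {
  stopifnot(inherits(q, "quant_matrix"))
  cols <- if (is.null(system)) {
    seq_len(ncol(q$intensity))
  } else {
    which(q$samples$system == system)
  }
  if (length(cols) == 0L) stop("no samples for system '", system, "'")
  m <- rowMeans(q$intensity[, cols, drop = FALSE], na.rm = TRUE)
  m[is.nan(m)] <- NA_real_
  m
}

#' Total Protein Approach copy numbers
#'
#' Converts raw intensities into absolute protein copies per cell. Each
#' protein's share of the summed raw intensity is taken as its share of the
#' cell's total protein mass; dividing that mass by the molecular weight and
#' multiplying by the Avogadro constant gives copies per cell:
#' \deqn{c_i = \frac{I_i}{\sum_j I_j} \cdot \frac{P_{cell} N_A}{MW_i}}
#' with \eqn{P_{cell}} the measured total protein content per cell (in grams
#' inside the formula) and \eqn{MW_i} in g/mol. Replicate columns of one
#' system are averaged (mean of non-missing raw intensities) before scaling.
#' The histone-ruler alternative is deliberately not offered: it is biased for
#' cell types with atypical DNA content (multinuclear hepatocytes, aneuploid
#' lines).
#'
#' @param q A `quant_matrix` whose samples (or the subset selected by
#'   `system`) belong to one cell system, or a named numeric vector of
#'   already-averaged intensities.
#' @param profile A `cell_system_profile` supplying the protein content.
#' @param mw Numeric vector of molecular weights (g/mol), parallel to the
#'   intensity rows; taken from `q$proteins$mw` when `q` is a `quant_matrix`.
#' @param system Optional system label to select columns from `q`.
#' @return Data frame with `accession`, `intensity_share`, and `copies_per_cell`
#'   (NA where the protein was never detected), with attributes
#'   `protein_per_cell_pg` and `system`.
#' @export
tpa_copy_numbers <- function(q, profile, mw = NULL, system = NULL) {
  stopifnot(inherits(profile, "cell_system_profile"))
  if (inherits(q, "quant_matrix")) {
    intensity <- mean_intensity(q, system = system)
    if (is.null(mw)) {
      if (!"mw" %in% names(q$proteins)) {
        stop("quant_matrix proteins table has no 'mw' column")
      }
      mw <- q$proteins$mw
    }
    accession <- q$proteins$accession
  } else {
    intensity <- q
    accession <- names(q)
    if (is.null(accession)) accession <- paste0("P", seq_along(q))
  }
  if (is.null(mw)) stop("molecular weights required")
  stopifnot(length(mw) == length(intensity))
  if (any(!is.na(intensity) & is.na(mw))) {
    stop("every quantified protein needs a molecular weight")
  }
  if (any(mw <= 0, na.rm = TRUE)) stop("molecular weights must be positive")
  if (all(is.na(intensity))) stop("all intensities missing: nothing to quantify")
  total <- sum(intensity, na.rm = TRUE)
  if (total <= 0) stop("summed intensity is zero: cannot form mass fractions")
  share <- intensity / total
  p_cell_g <- profile$protein_per_cell_pg * 1e-12
  copies <- share * p_cell_g * AVOGADRO / mw
  structure(
    data.frame(
      accession = accession,
      intensity_share = share,
      copies_per_cell = copies,
      row.names = NULL
    ),
    protein_per_cell_pg = profile$protein_per_cell_pg,
    system = profile$system_name
  )
}

#' Copy-number table across cell systems
#'
#' Binds per-system Total Protein Approach results into one proteins x systems
#' matrix of copies per cell, the unit of all downstream comparisons. Each
#' un-normalized column satisfies mass conservation:
#' sum(copies * mw) / N_A equals that system's protein content per cell.
#'
#' @param ... Named `tpa_copy_numbers()` results (names = system labels), or a
#'   single named list of them.
#' @param mw Molecular weights parallel to the shared protein order.
#' @return Object of class `copy_number_table`: list with `copies` matrix
#'   (proteins x systems), `mw`, `protein_per_cell_pg` per system, and
#'   `normalized` flag.
#' @export
copy_number_table <- function(..., mw) {
  cols <- list(...)
  if (length(cols) == 1L && !is.data.frame(cols[[1L]])) cols <- cols[[1L]]
  if (is.null(names(cols)) || any(!nzchar(names(cols)))) {
    names(cols) <- vapply(cols, attr, "", which = "system")
  }
  acc <- cols[[1L]]$accession
  for (cl in cols) {
    if (!identical(cl$accession, acc)) stop("copy-number columns must share protein order")
  }
  stopifnot(length(mw) == length(acc))
  copies <- vapply(cols, function(cl) cl$copies_per_cell, numeric(length(acc)))
  rownames(copies) <- acc
  structure(
    list(
      copies = copies,
      mw = mw,
      protein_per_cell_pg = vapply(cols, attr, 0, which = "protein_per_cell_pg"),
      normalized = FALSE,
      loess_span = NA_real_
    ),
    class = "copy_number_table"
  )
}

#' Check Total Protein Approach mass conservation
#'
#' For each un-normalized system column, the reconstructed protein mass
#' sum(copies_i * mw_i) / N_A (grams) must equal the measured protein content
#' per cell.
#'
#' @param tab A `copy_number_table`.
#' @return Named numeric vector of relative errors per system.
#' @export
mass_conservation_error <- function(tab) {
  stopifnot(inherits(tab, "copy_number_table"))
  vapply(seq_len(ncol(tab$copies)), function(j) {
    mass_pg <- sum(tab$copies[, j] * tab$mw, na.rm = TRUE) / AVOGADRO * 1e12
    abs(mass_pg - tab$protein_per_cell_pg[j]) / tab$protein_per_cell_pg[j]
  }, numeric(1L), USE.NAMES = FALSE) -> err
  names(err) <- colnames(tab$copies)
  err
}
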