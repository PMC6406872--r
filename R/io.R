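#' Read a protein FASTA file into an accession -> sequence map
#'
#' Parses UniProt-dialect headers (`>db|ACCESSION|ENTRY_NAME ...`), taking
#' the accession from the second pipe-separated field; plain headers fall
#' back to the first whitespace-delimited token. Sequences are uppercased
#' with whitespace stripped.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector: accession -> amino-acid sequence.
#' @export
read_fasta <- function(path) {
  seqs <- Biostrings::readAAStringSet(path)
  headers <- names(seqs)
  acc <- vapply(headers, function(h) {
    fields <- strsplit(h, "|", fixed = TRUE)[[1L]]
    if (length(fields) >= 2L) fields[2L] else strsplit(h, "\\s+")[[1L]][1L]
  }, character(1L), USE.NAMES = FALSE)
  if (anyDuplicated(acc)) {
    stop("duplicate accession(s) in FASTA: ",
         paste(unique(acc[duplicated(acc)]), collapse = ", "))
  }
  out <- toupper(gsub("[[:space:]]", "", as.character(seqs)))
  names(out) <- acc
  out
}

#' Read a MaxQuant-style proteinGroups table
#'
#' Expects a TSV with columns "Majority protein IDs", per-sample
#' "Intensity <sample>" columns, optional "MS/MS count <sample>" columns,
#' and the "Reverse" / "Potential contaminant" flag columns ("+" = flagged).
#' Flagged rows (decoys and contaminants) are removed by default; zero
#' intensities become missing values (the file convention for "not
#' detected"). Protein groups are identified by their leading (first-listed)
#' accession; when a FASTA map is supplied the molecular weight of that
#' leading accession's sequence is attached.
#'
#' @param path Path to the TSV.
#' @param fasta Optional named sequence vector from [read_fasta()] for
#'   molecular weights.
#' @param sample_meta Optional data frame of sample metadata with a
#'   `sample` column matching the intensity column suffixes.
#' @param remove_flagged Drop Reverse / Potential contaminant rows?
#'   Default TRUE.
#' @param intensity_prefix,msms_prefix Column-name prefixes, MaxQuant
#'   defaults.
#' @param permissive_mass Passed to [compute_molecular_weight()] for
#'   sequences with ambiguity codes.
#' @return A `quant_matrix`.
#' @export
read_protein_groups <- function(path, fasta = NULL, sample_meta = NULL,
                                remove_flagged = TRUE,
                                intensity_prefix = "Intensity ",
                                msms_prefix = "MS/MS count ",
                                permissive_mass = FALSE) {
  tab <- utils::read.delim(path, sep = "\t", check.names = FALSE,
                           comment.char = "#", stringsAsFactors = FALSE)
  if (!"Majority protein IDs" %in% names(tab)) {
    stop("missing mandatory column: 'Majority protein IDs'")
  }
  int_cols <- grep(paste0("^", intensity_prefix), names(tab), value = TRUE)
  # bare "Intensity" (summed) columns are not sample columns
  int_cols <- int_cols[nzchar(sub(paste0("^", intensity_prefix), "", int_cols))]
  if (length(int_cols) == 0L) {
    stop("missing mandatory columns: no '", intensity_prefix, "<sample>' columns")
  }
  if (remove_flagged) {
    flagged <- rep(FALSE, nrow(tab))
    for (fc in c("Reverse", "Potential contaminant")) {
      if (fc %in% names(tab)) {
        v <- tab[[fc]]
        flagged <- flagged | (!is.na(v) & v == "+")
      }
    }
    if (any(flagged)) {
      message("removed ", sum(flagged), " reverse/contaminant protein group(s)")
      tab <- tab[!flagged, , drop = FALSE]
    }
  }
  leading <- vapply(strsplit(tab[["Majority protein IDs"]], ";", fixed = TRUE),
                    `[`, character(1L), 1L)
  sample_names <- sub(paste0("^", intensity_prefix), "", int_cols)
  intensity <- as.matrix(tab[, int_cols, drop = FALSE])
  mode(intensity) <- "double"
  colnames(intensity) <- sample_names

  msms <- NULL
  msms_cols <- paste0(msms_prefix, sample_names)
  if (all(msms_cols %in% names(tab))) {
    msms <- as.matrix(tab[, msms_cols, drop = FALSE])
    mode(msms) <- "double"
    colnames(msms) <- sample_names
  }

  proteins <- data.frame(accession = leading, stringsAsFactors = FALSE)
  if (!is.null(fasta)) {
    seq_i <- fasta[leading]
    proteins$mw <- vapply(seq_along(seq_i), function(i) {
      if (is.na(seq_i[i])) return(NA_real_)
      compute_molecular_weight(seq_i[i], permissive = permissive_mass)
    }, numeric(1L))
  }
  samples <- data.frame(sample = sample_names, stringsAsFactors = FALSE)
  if (!is.null(sample_meta)) {
    if (!"sample" %in% names(sample_meta)) {
      stop("sample_meta needs a 'sample' column")
    }
    samples <- merge(samples, sample_meta, by = "sample", sort = FALSE)
    samples <- samples[match(sample_names, samples$sample), , drop = FALSE]
  }
  quant_matrix(intensity, proteins = proteins, samples = samples,
               msms_count = msms)
}

#' Write a result table as TSV with a provenance header
#'
#' Writes '#'-prefixed provenance comment lines (package version, written-at
#' parameters, user-supplied key = value pairs) followed by a plain
#' tab-separated table. [read_result_table()] round-trips these files;
#' the comment lines are ignored by every reader in the package.
#'
#' @param x Data frame.
#' @param path Output path.
#' @param params Named list/vector recorded as provenance lines.
#' @return Invisibly, `path`.
#' @export
write_result_table <- function(x, path, params = list()) {
  stopifnot(is.data.frame(x))
  lines <- c(
    paste0("# hepaquant ",
           as.character(utils::packageVersion("hepaquant"))),
    if (length(params)) {
      paste0("# ", names(params), " = ", vapply(params, format, character(1L)))
    }
  )
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(lines, con)
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_result_table()]
#'
#' @param path Path to the TSV; '#' comment lines are skipped.
#' @return Data frame.
#' @export
read_result_table <- function(path) {
  utils::read.delim(path, sep = "\t", comment.char = "#",
                    check.names = FALSE, stringsAsFactors = FALSE)
}
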