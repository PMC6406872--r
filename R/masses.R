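#' Average masses of amino-acid residues
#'
#' IUPAC average residue masses in g/mol (the free amino-acid mass minus one
#' water). Covers the 20 standard residues plus selenocysteine (U) and
#' pyrrolysine (O). Average, not monoisotopic, masses are used throughout
#' because Total Protein Approach scaling works with bulk protein mass.
#'
#' @format Named numeric vector, g/mol per residue.
#' @keywords internal
RESIDUE_MASS <- c(
  A =  71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G =  57.0513, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P =  97.1167,
  S =  87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V =  99.1326,
  U = 150.0388, O = 237.3018
)

#' Mass of one water molecule in g/mol, added once per peptide chain.
#' @keywords internal
WATER_MASS <- 18.0153

#' Avogadro constant, 1/mol (2019 SI exact value).
#' @keywords internal
AVOGADRO <- 6.02214076e23

#' Compute the average molecular weight of a protein sequence
#'
#' Sums average residue masses and adds one water mass for the termini.
#' Ambiguity codes B, Z and X are rejected by default because their mass is
#' undefined; with `permissive = TRUE` they are assigned a generic 110 g/mol
#' residue mass (roughly the proteome-average residue) and a warning is
#' emitted.
#'
#' @param sequence Character scalar, one-letter amino-acid codes. Case
#'   insensitive; whitespace is stripped.
#' @param permissive Substitute 110 g/mol for B/Z/X instead of erroring?
#' @return Average molecular mass in g/mol.
#' @examples
#' compute_molecular_weight("G")   # 75.0666
#' compute_molecular_weight("GG")  # 132.1179
#' @export
compute_molecular_weight <- function(sequence, permissive = FALSE) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(gsub("[[:space:]]", "", sequence))
  if (!nzchar(sequence)) {
    stop("empty protein sequence: molecular weight undefined")
  }
  residues <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  masses <- RESIDUE_MASS[residues]
  if (anyNA(masses)) {
    bad <- unique(residues[is.na(masses)])
    ambiguous <- bad %in% c("B", "Z", "X")
    if (permissive && all(ambiguous)) {
      warning(
        "ambiguous residue(s) ", paste(bad, collapse = ", "),
        " assigned generic mass 110 g/mol"
      )
      masses[is.na(masses)] <- 110.0
    } else {
      stop(
        "unrecognized residue code(s) in sequence: ",
        paste(bad, collapse = ", ")
      )
    }
  }
  sum(masses) + WATER_MASS
}
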