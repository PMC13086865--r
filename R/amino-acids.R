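# Residue-level constants shared across the package. All tables are keyed by
# the 20 standard one-letter codes; anything else is rejected at the door.

#' Standard amino-acid one-letter alphabet
#'
#' @return Character vector of the 20 standard residue letters.
#' @export
aa_alphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

# Average (not monoisotopic) residue masses in Da, i.e. the mass each residue
# contributes inside a chain; a free peptide adds one water.
.aa_residue_mass <- c(
  G = 57.0519, A = 71.0788, S = 87.0782, P = 97.1167, V = 99.1326,
  T = 101.1051, C = 103.1388, L = 113.1594, I = 113.1594, N = 114.1038,
  D = 115.0886, Q = 128.1307, K = 128.1741, E = 129.1155, M = 131.1926,
  H = 137.1411, F = 147.1766, R = 156.1875, Y = 163.1760, W = 186.2132
)

.water_mass <- 18.0153

# Kyte-Doolittle hydropathy index.
.aa_hydropathy <- c(
  A = 1.8, C = 2.5, D = -3.5, E = -3.5, F = 2.8, G = -0.4, H = -3.2,
  I = 4.5, K = -3.9, L = 3.8, M = 1.9, N = -3.5, P = -1.6, Q = -3.5,
  R = -4.5, S = -0.8, T = -0.7, V = 4.2, W = -0.9, Y = -1.3
)

# Formal side-chain charge at neutral pH; histidine counted half-protonated.
.aa_charge <- c(
  A = 0, C = 0, D = -1, E = -1, F = 0, G = 0, H = 0.5, I = 0, K = 1,
  L = 0, M = 0, N = 0, P = 0, Q = 0, R = 1, S = 0, T = 0, V = 0,
  W = 0, Y = 0
)

# Split a sequence string into residue letters, validating the alphabet.
aa_chars <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1L)
    stop("sequence must be a single character string")
  chars <- strsplit(toupper(sequence), "")[[1]]
  bad <- setdiff(unique(chars), aa_alphabet())
  if (length(bad))
    stop("non-standard residue letter(s): ", paste(bad, collapse = ", "))
  chars
}

#' Average molecular mass of a free peptide
#'
#' Sums standard average residue masses and adds one water (18.0153 Da) for
#' the free, unmodified termini. Additive over concatenation:
#' `average_mass(paste0(a, b)) == average_mass(a) + average_mass(b) - 18.0153`.
#'
#' @param sequence One-letter amino-acid string (standard residues only).
#'   The empty string returns the mass of water.
#' @return Mass in Da.
#' @examples
#' average_mass("EIVVQDGITLITKEEASGSSVTAEEAKK")  # ~2933 Da
#' @export
average_mass <- function(sequence) {
  if (identical(sequence, "")) return(.water_mass)
  chars <- aa_chars(sequence)
  sum(.aa_residue_mass[chars]) + .water_mass
}
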