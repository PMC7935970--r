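# Residue-level constant tables: masses, extinction coefficients,
# hydrophobicity. All sequences are one-letter, canonical 20 residues.

HEPTAD_ALPHABET <- c("a", "b", "c", "d", "e", "f", "g")

AA_CODES <- c(
  "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"
)

# Average residue masses (Da), IUPAC element weights; residue = amino acid
# minus one water. Free termini add one water to the chain sum.
AA_MASS_AVERAGE <- c(
  A = 71.0788, C = 103.1388, D = 115.0886, E = 129.1155, F = 147.1766,
  G = 57.0519, H = 137.1411, I = 113.1594, K = 128.1741, L = 113.1594,
  M = 131.1926, N = 114.1038, P = 97.1167, Q = 128.1307, R = 156.1875,
  S = 87.0782, T = 101.1051, V = 99.1326, W = 186.2132, Y = 163.1760
)

# Monoisotopic residue masses (Da).
AA_MASS_MONO <- c(
  A = 71.037114, C = 103.009185, D = 115.026943, E = 129.042593,
  F = 147.068414, G = 57.021464, H = 137.058912, I = 113.084064,
  K = 128.094963, L = 113.084064, M = 131.040485, N = 114.042927,
  P = 97.052764, Q = 128.058578, R = 156.101111, S = 87.032028,
  T = 101.047678, V = 99.068414, W = 186.079313, Y = 163.063329
)

MASS_WATER <- c(average = 18.01528, monoisotopic = 18.010565)

# Terminal / side-chain modification deltas (Da).
MOD_DELTAS <- list(
  average      = c(acetyl = 42.0367, amide = -0.9847, phospho = 79.9799),
  monoisotopic = c(acetyl = 42.010565, amide = -0.984016, phospho = 79.966331)
)

# Eisenberg consensus hydrophobicity scale (dimensionless).
HYDRO_EISENBERG <- c(
  A = 0.62, C = 0.29, D = -0.90, E = -0.74, F = 1.19, G = 0.48,
  H = -0.40, I = 1.38, K = -1.50, L = 1.06, M = 0.64, N = -0.78,
  P = 0.12, Q = -0.85, R = -2.53, S = -0.18, T = -0.05, V = 1.08,
  W = 0.81, Y = 0.26
)

#' Extinction coefficient table at 280 nm
#'
#' Per-chromophore molar extinction coefficients used by [epsilon280()].
#' Defaults are the standard solution values for tryptophan
#' (5690 M^-1 cm^-1) and tyrosine (1280 M^-1 cm^-1).
#'
#' @param eps280_trp Molar extinction coefficient of Trp at 280 nm.
#' @param eps280_tyr Molar extinction coefficient of Tyr at 280 nm.
#' @return An object of class `extinction_table`.
#' @export
extinction_table <- function(eps280_trp = 5690, eps280_tyr = 1280) {
  if (eps280_trp <= 0 || eps280_tyr <= 0) {
    stop("extinction coefficients must be strictly positive")
  }
  structure(list(eps280_trp = eps280_trp, eps280_tyr = eps280_tyr),
            class = "extinction_table")
}

# Validate a one-letter amino-acid string; returns the residue vector.
check_sequence <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1L || nchar(sequence) < 1L) {
    stop("sequence must be a single non-empty character string")
  }
  res <- strsplit(sequence, "")[[1]]
  bad <- which(!(res %in% AA_CODES))
  if (length(bad) > 0L) {
    stop(sprintf("non-canonical residue '%s' at position %d",
                 res[bad[1]], bad[1]))
  }
  res
}
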