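#' Molecular mass of a peptide or protein
#'
#' Chain mass = sum of residue masses + one water for free termini, plus
#' modification deltas (acetyl +42.0367, C-terminal amide -0.9847, phospho
#' +79.9799; average-mass values). The default convention is average
#' isotopic mass; monoisotopic is available via `convention`.
#'
#' @param entity A [registered_peptide()] or a plain one-letter sequence
#'   string (plain strings are treated as free/free, unmodified).
#' @param convention `"average"` (default) or `"monoisotopic"`.
#' @return Mass in Da.
#' @examples
#' molecular_mass("G") # glycine + water, 75.07 Da
#' @export
molecular_mass <- function(entity, convention = c("average", "monoisotopic")) {
  convention <- match.arg(convention)
  tab <- if (convention == "average") AA_MASS_AVERAGE else AA_MASS_MONO
  deltas <- MOD_DELTAS[[convention]]
  if (inherits(entity, "registered_peptide")) {
    res <- check_sequence(entity$sequence)
    m <- sum(tab[res]) + MASS_WATER[[convention]]
    if (entity$n_term_mod == "acetyl") m <- m + deltas[["acetyl"]]
    if (entity$c_term_mod == "amide") m <- m + deltas[["amide"]]
    if (!is.null(entity$sidechain_mods)) {
      for (mod in entity$sidechain_mods$mod) {
        if (!(mod %in% names(deltas))) stop(sprintf("unknown modification '%s'", mod))
        m <- m + deltas[[mod]]
      }
    }
    unname(m)
  } else {
    res <- check_sequence(entity)
    unname(sum(tab[res]) + MASS_WATER[[convention]])
  }
}

#' Masses of an expressed fusion with and without the initiator methionine
#'
#' Expressed proteins may retain the initiator Met or have it removed by
#' methionine aminopeptidase; both masses are reported so either can be
#' compared with an observed intact mass.
#'
#' @param sequence Plain one-letter sequence beginning with `M`.
#' @param convention Passed to [molecular_mass()].
#' @return Named numeric vector with `met_retained` and `met_cleaved` masses
#'   (the latter `NA` if the sequence does not start with Met).
#' @export
fusion_masses <- function(sequence, convention = "average") {
  res <- check_sequence(sequence)
  full <- molecular_mass(sequence, convention)
  clv <- if (res[1] == "M") {
    molecular_mass(paste(res[-1], collapse = ""), convention)
  } else NA_real_
  c(met_retained = full, met_cleaved = clv)
}

#' Molar extinction coefficient at 280 nm
#'
#' `eps280 = 5690 x (#Trp) + 1280 x (#Tyr)` with the default table; additive
#' over sequence concatenation. Disulfides are not modelled (the switch
#' peptides are Cys-free).
#'
#' @param sequence One-letter amino-acid string or [registered_peptide()].
#' @param table An [extinction_table()].
#' @return Extinction coefficient in M^-1 cm^-1.
#' @examples
#' epsilon280("WWYYY") # 2*5690 + 3*1280
#' @export
epsilon280 <- function(sequence, table = extinction_table()) {
  if (inherits(sequence, "registered_peptide")) sequence <- sequence$sequence
  res <- check_sequence(sequence)
  sum(res == "W") * table$eps280_trp + sum(res == "Y") * table$eps280_tyr
}
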