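# Bundled switch designs.
#
# The coiled-coil modules are reconstructed from the published design rules
# for the acidic/basic CC-Di-AB heterodimer family: four heptads of the
# E/K-patterned repeat (EIAALEQ / KIAALKQ, register gabcdef so that Ile sits
# at 'a' and the charged residues at 'e'/'g'), an Asn-Asn pair at 'a' of
# heptad 3 to set parallel register, Gly caps and a C-terminal Trp for
# concentration determination, acetyl/amide termini. The kinase-motif and
# a-a' variants are then derived with the package's own register operations:
# RRxS written so the acceptor Ser is at 'a' of heptad 2 with Arg-Arg at
# 'e'/'f' of heptad 1 (the identity of 'x' is the parent's residue), and the
# partner's corresponding a' Ile replaced by Ser.
#
# The membrane-targeting sequence and fusion-protein sequences shipped with
# the package are SYNTHETIC stand-ins (see synthetic_fusions.fasta): they
# have the right architecture (amphipathic 13-mer MTS; MTS/CC modules,
# fluorescent-protein-sized domain, oligohistidine tag and linkers) but are
# not the laboratory constructs.

CC_HEPTAD_A <- "EIAALEQ"
CC_HEPTAD_B <- "KIAALKQ"

# Four-heptad interaction module of the acidic (E) or basic (K) type with an
# Asn at 'a' of heptad `asn_heptad`.
cc_module_core <- function(type = c("acidic", "basic"), n_heptads = 4,
                           asn_heptad = 3) {
  type <- match.arg(type)
  rep_unit <- if (type == "acidic") CC_HEPTAD_A else CC_HEPTAD_B
  core <- paste(rep(rep_unit, n_heptads), collapse = "")
  p <- registered_peptide("module", core, register_offset = 6L)
  if (!is.null(asn_heptad)) {
    p <- substitute_at_register(p, "a", asn_heptad, "N", name = "module")
  }
  p$sequence
}

#' Reference switch peptide designs
#'
#' Builds the family of four-heptad coiled-coil switch peptides used
#' throughout the package: the acidic parent `CC-Di-A_N4` and its
#' destabilized variant `CC-Di-A_S` (a' Ile -> Ser at heptad 2), the basic
#' parent `CC-Di-B_N4`, the kinase-substrate variant `CC-Di-B_RRS`
#' (RRxS written with the acceptor Ser at 'a' of heptad 2) and its
#' phosphorylated form `CC-Di-B_RRpS`. Each peptide carries a Gly N-cap and
#' Gly-Trp C-cap outside the 28-residue heptad core, with acetyl/amide
#' termini. Sequences are reconstructions from the published design rules,
#' not transcriptions (see the package vignette).
#'
#' @return Named list of [registered_peptide()] objects.
#' @export
cc_switch_peptides <- function() {
  cap_peptide <- function(name, core, mods = NULL) {
    registered_peptide(
      name = name,
      sequence = paste0("G", core, "GW"),
      register_offset = 6L,            # first core residue at 'g'
      core = c(2L, 1L + nchar(core)),
      n_term_mod = "acetyl", c_term_mod = "amide",
      sidechain_mods = mods
    )
  }
  a_n4 <- cap_peptide("CC-Di-A_N4", cc_module_core("acidic"))
  b_n4 <- cap_peptide("CC-Di-B_N4", cc_module_core("basic"))
  a_s <- substitute_at_register(a_n4, "a", 2, "S", name = "CC-Di-A_S")
  b_rrs <- insert_kinase_motif(b_n4, "RRxS", "a", 2, name = "CC-Di-B_RRS")
  ser_idx <- seq_index_of(b_rrs, "a", 2)
  b_rrps <- registered_peptide(
    name = "CC-Di-B_RRpS", sequence = b_rrs$sequence,
    register_offset = b_rrs$register_offset, core = b_rrs$core,
    n_term_mod = b_rrs$n_term_mod, c_term_mod = b_rrs$c_term_mod,
    sidechain_mods = data.frame(index = ser_idx, mod = "phospho")
  )
  list(`CC-Di-A_N4` = a_n4, `CC-Di-A_S` = a_s, `CC-Di-B_N4` = b_n4,
       `CC-Di-B_RRS` = b_rrs, `CC-Di-B_RRpS` = b_rrps)
}

#' Synthetic amphipathic membrane-targeting sequence
#'
#' A 13-residue stand-in for a weak, Trp-containing amphipathic
#' membrane-targeting helix of the type used in avidity switches: hydrophobic
#' residues (M/L/W/I/F) on the a/d/e wheel face, polar residues elsewhere.
#' It is a designed synthetic sequence, not a natural one.
#'
#' @return A [registered_peptide()].
#' @export
synthetic_mts <- function() {
  registered_peptide("MTS-syn", "MSKLWSKISKLFS", register_offset = 0L)
}

#' Synthetic fusion construct stand-ins
#'
#' Reads the bundled `synthetic_fusions.fasta`: three fusion-protein
#' sequences with the architecture of the membrane-switch constructs
#' (anchor = CC-A module + linker + fluorescent-protein-sized domain + His10;
#' switches = MTS + domain + His6 + CC module) assembled around a fixed
#' synthetic stand-in domain. Intended for exercising the mass and design
#' pipeline; they are not the laboratory constructs and their masses are not
#' expected to equal published values.
#'
#' @return Named character vector of plain sequences.
#' @export
synthetic_fusions <- function() {
  path <- system.file("extdata", "synthetic_fusions.fasta",
                      package = "ccswitch", mustWork = TRUE)
  set <- Biostrings::readAAStringSet(path)
  stats::setNames(as.character(set),
                  vapply(strsplit(names(set), "\\s+"), `[[`, "", 1))
}
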