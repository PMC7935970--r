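#' Helical wheel layout for a registered peptide
#'
#' Places each core residue on a single-turn wheel at
#' `angle = (i - 1) * degrees_per_residue mod 360`. The default step of
#' 102.857 deg/residue (3.5 residues per turn) is the coiled-coil-adapted
#' wheel, on which the seven register positions fall at seven fixed angles
#' and residues seven apart superimpose, with `a` and `d` in adjacent
#' sectors forming the hydrophobic seam.
#'
#' @param peptide A [registered_peptide()] with core length >= 7.
#' @param degrees_per_residue Angular step; default `360 * 3.5^-1`.
#' @return A data frame (class `wheel_layout`) with columns `index`
#'   (position in the full sequence), `residue`, `register`, `angle_deg`, and
#'   `hydrophobic` (Eisenberg consensus > 0).
#' @export
helical_wheel <- function(peptide, degrees_per_residue = 360 / 3.5) {
  stopifnot(inherits(peptide, "registered_peptide"))
  idx <- seq(peptide$core[1], peptide$core[2])
  if (length(idx) < 7L) stop("peptide core must contain at least 7 residues")
  res <- strsplit(peptide$sequence, "")[[1]][idx]
  reg <- registers(peptide)[idx]
  ang <- ((seq_along(idx) - 1) * degrees_per_residue) %% 360
  out <- data.frame(index = idx, residue = res, register = reg,
                    angle_deg = ang,
                    hydrophobic = HYDRO_EISENBERG[res] > 0,
                    row.names = NULL)
  class(out) <- c("wheel_layout", "data.frame")
  out
}

#' Hydrophobic moment of a registered peptide
#'
#' First moment of the hydrophobicity profile around the helix axis:
#' `mu = | sum_i H_i exp(i * theta_i) |` with `theta_i` the wheel angle of
#' residue i. Uses the wheel step of [helical_wheel()] so the moment is
#' invariant under rotating the sequence by whole turns (7 residues at the
#' default step). A large moment relative to scrambled sequences indicates
#' amphipathic segregation, the property membrane-targeting sequences rely
#' on.
#'
#' @param peptide A [registered_peptide()] (core length >= 7) or a plain
#'   sequence string.
#' @param scale Named per-residue hydrophobicity vector covering every
#'   residue present; default Eisenberg consensus.
#' @param degrees_per_residue Angular step, as in [helical_wheel()].
#' @return List with `moment` (magnitude), `direction_deg` (angle of the
#'   moment vector), and `mean_hydrophobicity`.
#' @export
hydrophobic_moment <- function(peptide, scale = HYDRO_EISENBERG,
                               degrees_per_residue = 360 / 3.5) {
  if (inherits(peptide, "registered_peptide")) {
    idx <- seq(peptide$core[1], peptide$core[2])
    res <- strsplit(peptide$sequence, "")[[1]][idx]
  } else {
    res <- check_sequence(peptide)
  }
  if (length(res) < 7L) stop("need at least 7 residues")
  missing <- setdiff(unique(res), names(scale))
  if (length(missing) > 0) {
    stop(sprintf("hydrophobicity scale lacks residue(s): %s",
                 paste(missing, collapse = ", ")))
  }
  h <- scale[res]
  th <- (seq_along(res) - 1) * degrees_per_residue * pi / 180
  vx <- sum(h * cos(th))
  vy <- sum(h * sin(th))
  list(moment = sqrt(vx^2 + vy^2),
       direction_deg = (atan2(vy, vx) * 180 / pi) %% 360,
       mean_hydrophobicity = mean(h))
}
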