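#' Load an a-a' pairing-energy table
#'
#' Relative coupling free energies (kcal/mol, more negative = more
#' stabilizing) for residue pairs at the facing `a`-`a'` sites of a parallel
#' coiled-coil dimer. The table is symmetrized on load and validated:
#' Ile-Ile must be the global minimum of the table. The shipped default
#' carries order-calibrated placeholder values that encode the established
#' ordinal relations (Ile-Ile most stabilizing; Ser-Ile the least
#' destabilizing Ser pairing; Ser-Ser preferred among Ser-polar pairings);
#' absolute values are user-replaceable via `path`.
#'
#' @param path CSV with columns `res_a,res_aprime,energy[,source]`; default
#'   the shipped table.
#' @return A symmetric numeric matrix of class `pairing_table` with a
#'   `source` attribute.
#' @export
pairing_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "pairing_table.csv", package = "ccswitch",
                        mustWork = TRUE)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("res_a", "res_aprime", "energy") %in% names(df)))
  res <- sort(unique(c(df$res_a, df$res_aprime)))
  m <- matrix(NA_real_, length(res), length(res), dimnames = list(res, res))
  for (i in seq_len(nrow(df))) {
    a <- df$res_a[i]; b <- df$res_aprime[i]; e <- df$energy[i]
    if (!is.na(m[a, b]) && m[a, b] != e) {
      stop(sprintf("pairing table is asymmetric for %s-%s", a, b))
    }
    m[a, b] <- e
    m[b, a] <- e
  }
  if (!identical(m, t(m))) stop("pairing table must be symmetric")
  ii <- m["I", "I"]
  if (!all(ii <= m[!is.na(m)])) {
    stop("pairing table violates the Ile-Ile minimum invariant")
  }
  structure(m, class = c("pairing_table", class(m)),
            source = if ("source" %in% names(df)) unique(df$source) else NA)
}

#' Score an a-a' residue pairing
#'
#' @param res_a,res_aprime One-letter codes of the residues at the facing
#'   `a` sites (the score is symmetric).
#' @param table A [pairing_table()].
#' @return Relative coupling energy (kcal/mol; more negative = more
#'   stabilizing).
#' @export
score_pairing <- function(res_a, res_aprime, table = pairing_table()) {
  avail <- rownames(table)
  for (r in c(res_a, res_aprime)) {
    if (!(r %in% avail) || is.na(table[res_a, res_aprime])) {
      stop(sprintf("no pairing entry for %s-%s; tabulated residues: %s",
                   res_a, res_aprime, paste(avail, collapse = ", ")))
    }
  }
  unname(table[res_a, res_aprime])
}

#' Rank candidate a' residues against a switch peptide's interface residue
#'
#' Reads the residue at the given register address of the basic peptide
#' (typically the phospho-acceptor Ser at `a` of heptad 2) and ranks
#' candidate partner residues by [score_pairing()], most stabilizing first;
#' ties break alphabetically.
#'
#' @param b_peptide A [registered_peptide()].
#' @param candidate_a_residues Character vector of candidate one-letter codes.
#' @param table A [pairing_table()].
#' @param register,heptad Register address of the interface residue on
#'   `b_peptide` (default `a` of heptad 2).
#' @return Data frame `candidate`, `energy`, `rank`, ordered by rank; the
#'   interface residue is attached as attribute `interface_residue`.
#' @export
rank_partner_variants <- function(b_peptide, candidate_a_residues,
                                  table = pairing_table(),
                                  register = "a", heptad = 2) {
  stopifnot(inherits(b_peptide, "registered_peptide"))
  i <- seq_index_of(b_peptide, register, heptad)
  res_b <- strsplit(b_peptide$sequence, "")[[1]][i]
  energy <- vapply(candidate_a_residues, score_pairing, numeric(1),
                   res_aprime = res_b, table = table)
  ord <- order(energy, candidate_a_residues)
  out <- data.frame(candidate = candidate_a_residues[ord],
                    energy = unname(energy[ord]),
                    rank = seq_along(ord), row.names = NULL)
  attr(out, "interface_residue") <- res_b
  out
}
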