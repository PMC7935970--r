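#' Registered coiled-coil peptide
#'
#' A peptide sequence annotated with a heptad register. `register_offset`
#' follows the convention that offset 0 places the first core residue at
#' heptad position `a`; position of core residue `i` is
#' `heptad_alphabet[(offset + i - 1) mod 7]`. Residues outside the `core`
#' window (caps, linkers) carry register `"-"` and are excluded from wheel
#' and pairing logic.
#'
#' @param name Text label.
#' @param sequence One-letter amino-acid string (canonical 20 residues).
#' @param register_offset Integer 0-6; see Details.
#' @param core Integer length-2 vector `c(start, end)` (1-based, inclusive)
#'   delimiting the heptad-registered segment. Default: whole sequence.
#' @param n_term_mod `"free"` or `"acetyl"`.
#' @param c_term_mod `"free"` or `"amide"`.
#' @param sidechain_mods Data frame with columns `index` (1-based position in
#'   `sequence`) and `mod` (currently `"phospho"`), or `NULL`.
#' @return An object of class `registered_peptide`.
#' @export
registered_peptide <- function(name, sequence, register_offset = 0L,
                               core = NULL,
                               n_term_mod = c("free", "acetyl"),
                               c_term_mod = c("free", "amide"),
                               sidechain_mods = NULL) {
  res <- check_sequence(sequence)
  n <- length(res)
  n_term_mod <- match.arg(n_term_mod)
  c_term_mod <- match.arg(c_term_mod)
  if (!(register_offset %in% 0:6)) stop("register_offset must be in 0..6")
  if (is.null(core)) core <- c(1L, n)
  core <- as.integer(core)
  if (length(core) != 2L || core[1] < 1L || core[2] > n || core[1] > core[2]) {
    stop("core must be c(start, end) within the sequence")
  }
  if (!is.null(sidechain_mods)) {
    stopifnot(is.data.frame(sidechain_mods),
              all(c("index", "mod") %in% names(sidechain_mods)))
    for (j in seq_len(nrow(sidechain_mods))) {
      idx <- sidechain_mods$index[j]
      mod <- sidechain_mods$mod[j]
      if (idx < 1L || idx > n) {
        stop(sprintf("sidechain modification index %d outside sequence", idx))
      }
      if (mod == "phospho" && !(res[idx] %in% c("S", "T", "Y"))) {
        stop(sprintf("phospho at position %d requires S, T or Y (found %s)",
                     idx, res[idx]))
      }
      if (!(mod %in% c("phospho"))) stop(sprintf("unknown modification '%s'", mod))
    }
  }
  structure(
    list(name = name, sequence = sequence,
         register_offset = as.integer(register_offset), core = core,
         n_term_mod = n_term_mod, c_term_mod = c_term_mod,
         sidechain_mods = sidechain_mods),
    class = "registered_peptide"
  )
}

#' @export
print.registered_peptide <- function(x, ...) {
  cat(sprintf("<registered_peptide> %s (%d aa)\n", x$name, nchar(x$sequence)))
  cat(" ", x$sequence, "\n ", paste(registers(x), collapse = ""), "\n", sep = "")
  cat(sprintf("  N-term: %s  C-term: %s\n", x$n_term_mod, x$c_term_mod))
  if (!is.null(x$sidechain_mods) && nrow(x$sidechain_mods) > 0) {
    cat("  mods:", paste(sprintf("%s@%d", x$sidechain_mods$mod,
                                 x$sidechain_mods$index), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Assign heptad register positions to a sequence
#'
#' Pure register bookkeeping: residue `i` maps to
#' `heptad_alphabet[(register_offset + i - 1) mod 7]`, so the assignment is
#' periodic with period 7.
#'
#' @param sequence One-letter amino-acid string.
#' @param register_offset Integer 0-6; 0 puts residue 1 at `a`.
#' @return Character vector of heptad positions, one per residue.
#' @examples
#' assign_register("EIAALEQ", 6) # gabcdef
#' @export
assign_register <- function(sequence, register_offset = 0L) {
  res <- check_sequence(sequence)
  if (!(register_offset %in% 0:6)) stop("register_offset must be in 0..6")
  HEPTAD_ALPHABET[((register_offset + seq_along(res) - 1L) %% 7L) + 1L]
}

#' Per-residue register of a registered peptide
#'
#' Residues outside the core window are reported as `"-"`.
#'
#' @param peptide A [registered_peptide()].
#' @return Character vector, one entry per residue of the full sequence.
#' @export
registers <- function(peptide) {
  stopifnot(inherits(peptide, "registered_peptide"))
  n <- nchar(peptide$sequence)
  out <- rep("-", n)
  idx <- seq(peptide$core[1], peptide$core[2])
  out[idx] <- HEPTAD_ALPHABET[((peptide$register_offset +
                                  seq_along(idx) - 1L) %% 7L) + 1L]
  out
}

# Core-relative index of heptad position `register` in heptad `heptad_index`.
# Heptads are counted so that heptad k's 'a' is the (k-th) a position; residues
# preceding the first 'a' belong to heptad 0.
core_index_of <- function(peptide, register, heptad_index) {
  pos <- match(register, HEPTAD_ALPHABET)
  if (is.na(pos)) stop("register must be one of a..g")
  7L * as.integer(heptad_index) + pos - peptide$register_offset
}

# Absolute (full-sequence) index of a register/heptad address.
seq_index_of <- function(peptide, register, heptad_index) {
  ci <- core_index_of(peptide, register, heptad_index)
  peptide$core[1] + ci - 1L
}

#' Heptad index of each residue
#'
#' @param peptide A [registered_peptide()].
#' @return Integer vector (NA outside the core); heptad k starts at its `a`
#'   position, residues before the first `a` carry heptad 0.
#' @export
heptad_index <- function(peptide) {
  stopifnot(inherits(peptide, "registered_peptide"))
  n <- nchar(peptide$sequence)
  out <- rep(NA_integer_, n)
  idx <- seq(peptide$core[1], peptide$core[2])
  out[idx] <- (peptide$register_offset + seq_along(idx) - 1L) %/% 7L
  out
}

#' Insert a kinase recognition motif at a chosen register address
#'
#' Writes a phosphorylation motif such as `"RRxS"` into a parent peptide so
#' that the phospho-acceptor (the final S/T of the motif) lands at
#' `anchor_register` of heptad `heptad_index`. Motif positions `x`/`X` keep
#' the parent residue. With the acceptor at `a` of heptad k, the two
#' arginines of `RRxS` fall at `e` and `f` of heptad k-1, the positions
#' furthest from the hydrophobic interface.
#'
#' @param parent A [registered_peptide()].
#' @param motif Character motif ending in the acceptor residue, e.g. `"RRxS"`.
#' @param anchor_register Heptad position (`"a"`..`"g"`) for the acceptor.
#' @param heptad_index Which heptad the acceptor sits in.
#' @param name Optional name for the derived peptide.
#' @return A new `registered_peptide` differing from the parent only at the
#'   non-`x` motif positions.
#' @export
insert_kinase_motif <- function(parent, motif, anchor_register, heptad_index,
                                name = NULL) {
  stopifnot(inherits(parent, "registered_peptide"))
  mres <- strsplit(motif, "")[[1]]
  acceptor <- mres[length(mres)]
  if (!(acceptor %in% c("S", "T", "x", "X"))) {
    stop("motif must end in the phospho-acceptor residue (S or T)")
  }
  i_acc <- seq_index_of(parent, anchor_register, heptad_index)
  span <- seq(i_acc - length(mres) + 1L, i_acc)
  n <- nchar(parent$sequence)
  if (span[1] < 1L || span[length(span)] > n) {
    clipped <- span[span < 1L | span > n]
    stop(sprintf("motif overruns the peptide terminus (positions %s)",
                 paste(clipped, collapse = ", ")))
  }
  res <- strsplit(parent$sequence, "")[[1]]
  keep <- mres %in% c("x", "X")
  res[span[!keep]] <- mres[!keep]
  registered_peptide(
    name = if (is.null(name)) paste0(parent$name, "+", motif) else name,
    sequence = paste(res, collapse = ""),
    register_offset = parent$register_offset, core = parent$core,
    n_term_mod = parent$n_term_mod, c_term_mod = parent$c_term_mod,
    sidechain_mods = parent$sidechain_mods
  )
}

#' Substitute a single residue addressed by register and heptad
#'
#' @param parent A [registered_peptide()].
#' @param register Heptad position (`"a"`..`"g"`).
#' @param heptad_index Which heptad.
#' @param new_residue One-letter code for the replacement.
#' @param name Optional name for the derived peptide.
#' @return A new `registered_peptide` with exactly one position changed (or
#'   identical sequence if the residue is already present); register
#'   annotation unchanged.
#' @export
substitute_at_register <- function(parent, register, heptad_index, new_residue,
                                   name = NULL) {
  stopifnot(inherits(parent, "registered_peptide"))
  if (!(new_residue %in% AA_CODES)) {
    stop(sprintf("'%s' is not a canonical residue", new_residue))
  }
  i <- seq_index_of(parent, register, heptad_index)
  n <- nchar(parent$sequence)
  if (i < 1L || i > n) {
    stop(sprintf("register %s of heptad %d is outside the peptide (index %d)",
                 register, heptad_index, i))
  }
  res <- strsplit(parent$sequence, "")[[1]]
  res[i] <- new_residue
  registered_peptide(
    name = if (is.null(name)) {
      sprintf("%s_%s%d%s", parent$name, register, heptad_index, new_residue)
    } else name,
    sequence = paste(res, collapse = ""),
    register_offset = parent$register_offset, core = parent$core,
    n_term_mod = parent$n_term_mod, c_term_mod = parent$c_term_mod,
    sidechain_mods = parent$sidechain_mods
  )
}

# ---- FASTA input/output -----------------------------------------------------
# Header grammar: ">name key=value ..." with keys offset, core (start-end),
# nterm, cterm, mods (comma-separated idx:mod tokens).

#' Write registered peptides to FASTA
#'
#' Register and modification annotations are encoded as `key=value` tokens on
#' the description line (`offset=`, `core=start-end`, `nterm=`, `cterm=`,
#' `mods=idx:mod,...`).
#'
#' @param peptides A list of [registered_peptide()] objects.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_peptides_fasta <- function(peptides, path) {
  if (inherits(peptides, "registered_peptide")) peptides <- list(peptides)
  desc <- vapply(peptides, function(p) {
    tokens <- c(
      gsub("\\s+", "_", p$name),
      sprintf("offset=%d", p$register_offset),
      sprintf("core=%d-%d", p$core[1], p$core[2]),
      sprintf("nterm=%s", p$n_term_mod),
      sprintf("cterm=%s", p$c_term_mod)
    )
    if (!is.null(p$sidechain_mods) && nrow(p$sidechain_mods) > 0) {
      tokens <- c(tokens, sprintf("mods=%s", paste(
        sprintf("%d:%s", p$sidechain_mods$index, p$sidechain_mods$mod),
        collapse = ",")))
    }
    paste(tokens, collapse = " ")
  }, character(1))
  seqs <- Biostrings::AAStringSet(vapply(peptides, `[[`, character(1), "sequence"))
  names(seqs) <- desc
  Biostrings::writeXStringSet(seqs, filepath = path)
  invisible(path)
}

#' Read registered peptides from FASTA
#'
#' @param path FASTA file written by [write_peptides_fasta()] (plain FASTA is
#'   accepted; missing annotation tokens fall back to defaults).
#' @return A named list of [registered_peptide()] objects.
#' @export
read_peptides_fasta <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  out <- lapply(seq_along(set), function(i) {
    tokens <- strsplit(names(set)[i], "\\s+")[[1]]
    nm <- tokens[1]
    kv <- tokens[-1]
    get_tok <- function(key, default) {
      hit <- grep(paste0("^", key, "="), kv, value = TRUE)
      if (length(hit) == 0) default else sub(paste0("^", key, "="), "", hit[1])
    }
    seqc <- as.character(set[[i]])
    core_tok <- get_tok("core", sprintf("1-%d", nchar(seqc)))
    core <- as.integer(strsplit(core_tok, "-")[[1]])
    mods_tok <- get_tok("mods", "")
    mods <- NULL
    if (nzchar(mods_tok)) {
      parts <- strsplit(strsplit(mods_tok, ",")[[1]], ":")
      mods <- data.frame(index = vapply(parts, function(p) as.integer(p[1]), 1L),
                         mod = vapply(parts, function(p) p[2], ""))
    }
    registered_peptide(
      name = nm, sequence = seqc,
      register_offset = as.integer(get_tok("offset", "0")),
      core = core,
      n_term_mod = get_tok("nterm", "free"),
      c_term_mod = get_tok("cterm", "free"),
      sidechain_mods = mods
    )
  })
  names(out) <- vapply(out, `[[`, character(1), "name")
  out
}
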