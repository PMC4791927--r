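# Bridge to Open Babel via ChemmineOB: format conversion, canonical SMILES,
# SYBYL mol2 atom typing, FP2 fingerprints and whole-molecule descriptors.
# All calls are batched (one conversion per set of molecules) because the
# per-call overhead dominates for the small graphs handled during synthesis.

#' @noRd
ob_convert <- function(from, to, text) {
  ChemmineOB::convertFormat(from, to, source = text)
}

#' Canonical SMILES keys for a set of molecular graphs
#'
#' Computes the canonical SMILES of each graph through Open Babel's `can`
#' output format. The key of a molecule is independent of atom input order:
#' isomorphic typed graphs yield byte-identical keys.
#'
#' @param mols a `molecule_graph` or list of them.
#' @return Character vector of canonical SMILES, one per molecule.
#' @export
canonical_keys <- function(mols) {
  if (inherits(mols, "molecule_graph")) mols <- list(mols)
  if (length(mols) == 0L) return(character())
  tagged <- lapply(seq_along(mols), function(k) {
    m <- mols[[k]]; m$name <- sprintf("m%d", k); m
  })
  out <- ob_convert("SDF", "CAN", sdf_text(tagged))
  lines <- strsplit(out, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(trimws(lines))]
  smi <- sub("[ \t].*$", "", lines)
  ttl <- sub("^[^ \t]*[ \t]+", "", lines)
  ttl[ttl == lines] <- ""
  keys <- rep(NA_character_, length(mols))
  idx <- suppressWarnings(as.integer(sub("^m", "", trimws(ttl))))
  ok <- !is.na(idx) & idx >= 1L & idx <= length(mols)
  keys[idx[ok]] <- smi[ok]
  if (anyNA(keys)) {
    stop("canonical SMILES generation failed for ",
         sum(is.na(keys)), " molecule(s)", call. = FALSE)
  }
  keys
}

#' Canonical SMILES key of one molecular graph
#'
#' @param mol a `molecule_graph`.
#' @return Canonical SMILES string.
#' @export
canonical_key <- function(mol) {
  canonical_keys(list(mol))[[1]]
}

#' Assign SYBYL atom types to molecular graphs
#'
#' Types every atom with its SYBYL chemical type (C.3, C.ar, N.am, O.co2, ...)
#' as perceived by Open Babel's mol2 writer; aromaticity perception is
#' delegated to the toolkit's default model. Assignment is deterministic and
#' idempotent. Atoms whose type falls outside the supported closed set make
#' the molecule untypable.
#'
#' @param mols a `molecule_graph` or list of them.
#' @param strict error (TRUE) or return NA types (FALSE) for unsupported types.
#' @return The input list with the `sybyl` atom column filled (single graph in,
#'   single graph out).
#' @export
assign_sybyl_types <- function(mols, strict = TRUE) {
  single <- inherits(mols, "molecule_graph")
  if (single) mols <- list(mols)
  if (length(mols) == 0L) return(mols)
  m2 <- ob_convert("SDF", "MOL2", sdf_text(mols))
  blocks <- strsplit(m2, "@<TRIPOS>MOLECULE", fixed = TRUE)[[1]]
  blocks <- blocks[-1]
  if (length(blocks) != length(mols)) {
    stop("mol2 conversion returned ", length(blocks), " records for ",
         length(mols), " molecules", call. = FALSE)
  }
  for (k in seq_along(mols)) {
    lines <- strsplit(blocks[[k]], "\n", fixed = TRUE)[[1]]
    i1 <- grep("@<TRIPOS>ATOM", lines, fixed = TRUE)[1]
    after <- grep("@<TRIPOS>", lines, fixed = TRUE)
    i2 <- c(after[after > i1], length(lines) + 1L)[1]
    rows <- trimws(lines[(i1 + 1L):(i2 - 1L)])
    rows <- rows[nzchar(rows)]
    ty <- vapply(strsplit(rows, "\\s+"), function(z) z[6], character(1))
    ty <- ty[ty != "H"]
    if (length(ty) != n_atoms(mols[[k]])) {
      stop("mol2 atom count mismatch for molecule ", k, call. = FALSE)
    }
    bad <- !is_supported_sybyl(ty)
    if (any(bad)) {
      if (strict) {
        stop(sprintf("untypable atom %d (%s) in molecule %s",
                     which(bad)[1], ty[which(bad)[1]],
                     if (nzchar(mols[[k]]$name)) mols[[k]]$name else k),
             call. = FALSE)
      }
      ty[bad] <- NA_character_
    }
    mols[[k]]$atoms$sybyl <- ty
  }
  if (single) mols[[1]] else mols
}

#' FP2 fingerprint matrix for a set of molecular graphs
#'
#' Hashed path-based (Open Babel FP2) fingerprints, one row per molecule.
#'
#' @param mols a `molecule_graph` or list of them.
#' @return 0/1 matrix with 1024 columns.
#' @export
fingerprint_matrix <- function(mols) {
  if (inherits(mols, "molecule_graph")) mols <- list(mols)
  handle <- ChemmineOB:::OBFingerprint_FindFingerprint("FP2")
  fps <- ChemmineOB::forEachMol("SDF", sdf_text(mols), function(m) {
    words <- ChemmineOB:::OBFingerprint_GetFingerprint(handle, m,
                                                       numeric(1))[[2]]
    # 32-bit fingerprint words may arrive signed, unsigned-in-double, or as
    # NA (the INT_MIN pattern, i.e. only bit 31 set); normalize to unsigned
    u <- as.numeric(words)
    u[is.na(u)] <- 2^31
    u[u < 0] <- u[u < 0] + 2^32
    hi <- u >= 2^31
    bits <- as.integer(intToBits(as.integer(u - ifelse(hi, 2^31, 0))))
    bits[seq_along(u) * 32L] <- bits[seq_along(u) * 32L] + as.integer(hi)
    bits
  })
  do.call(rbind, fps)
}

#' Whole-molecule descriptors via Open Babel
#'
#' Returns Open Babel's descriptor table (logP by atomic contributions, MW,
#' HBA/HBD counts, TPSA, canonical SMILES) for each graph.
#'
#' @param mols a `molecule_graph` or list of them.
#' @return data.frame, one row per molecule.
#' @export
ob_descriptors <- function(mols) {
  if (inherits(mols, "molecule_graph")) mols <- list(mols)
  props <- ChemmineOB::forEachMol("SDF", sdf_text(mols), function(m) {
    ChemmineOB::prop_OB(m)
  })
  do.call(rbind, props)
}

#' Canonical atom ranks for a molecular graph
#'
#' Position of each atom in Open Babel's canonical atom ordering; used to
#' align attachment atoms between duplicate fragments during consolidation
#' and to build canonical open-connection state signatures during synthesis.
#'
#' @param mol a `molecule_graph`.
#' @return Integer vector: `rank[i]` is the canonical position of atom i.
#' @export
canonical_ranks <- function(mol) {
  ranks <- ChemmineOB::forEachMol("SDF", sdf_text(list(mol)), function(m) {
    ChemmineOB::canonicalNumbering_OB(m)
  })[[1]][[1]]
  r <- as.integer(unlist(ranks))
  if (length(r) != n_atoms(mol) || anyDuplicated(r)) {
    # fall back to identity should canonical perception fail
    r <- seq_len(n_atoms(mol))
  }
  r
}
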