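# Consolidation of fragments from many parents into a non-redundant library.
# Fragment identity is the canonical SMILES of the saturated fragment graph
# (within a kind); connection annotations of duplicates are merged through
# the canonical atom ordering, with symmetry-equivalent atoms sharing the
# merged annotation so that the result is independent of input order and of
# the particular automorphism the canonicalizer picked for each copy.

#' Put a molecular graph into canonical atom order
#' @noRd
canonical_form <- function(mol) {
  permute_atoms(mol, order(canonical_ranks(mol)))
}

#' Symmetry classes of a molecular graph
#'
#' Equivalence classes of atoms under iterated Weisfeiler-Lehman colour
#' refinement seeded with (element, SYBYL type, charge, hydrogen count).
#' Symmetric atoms (for example the two ortho positions of a monosubstituted
#' ring) receive the same class id; class ids are canonical strings,
#' independent of atom input order.
#'
#' @param mol a `molecule_graph`.
#' @param extra optional extra per-atom labels folded into the seed colours
#'   (used to make classes respect open-connection state during synthesis).
#' @return Character vector of class ids, one per atom.
#' @export
symmetry_classes <- function(mol, extra = NULL) {
  a <- mol$atoms
  col <- paste(a$element, a$sybyl, a$charge, a$hcount, sep = "|")
  if (!is.null(extra)) col <- paste(col, extra, sep = "|")
  nb <- neighbor_list(mol)
  bord <- vector("list", nrow(a))
  b <- mol$bonds
  for (k in seq_len(nrow(b))) {
    bord[[b$i[k]]] <- c(bord[[b$i[k]]], b$order[k])
    bord[[b$j[k]]] <- c(bord[[b$j[k]]], b$order[k])
  }
  repeat {
    nxt <- vapply(seq_len(nrow(a)), function(i) {
      if (length(nb[[i]]) == 0L) return(col[i])
      env <- sort(paste0(bord[[i]], ":", col[nb[[i]]]))
      paste0(col[i], "{", paste(env, collapse = ","), "}")
    }, character(1))
    if (length(unique(nxt)) == length(unique(col)) &&
        identical(as.integer(factor(nxt)), as.integer(factor(col)))) break
    col <- nxt
  }
  # compress to short canonical ids (ordered by the underlying colour string)
  lev <- sort(unique(col))
  paste0("s", match(col, lev))
}

#' Consolidate fragments into a non-redundant library
#'
#' Fragments with the same kind and canonical key are merged into one entry:
#' rigid attachment-type sets are unioned and linker original-connection
#' counts take the per-atom maximum, with attachment atoms matched through
#' the canonical atom ordering and symmetry-equivalent atoms sharing the
#' merged annotation. Provenance is unioned. Consolidation is idempotent and
#' independent of input order.
#'
#' @param fragments list of annotated `esynth_fragment` objects (or an
#'   `esynth_decomposition`, whose fragments are used).
#' @param linker_mode `"saturated"` or `"unsaturated"` connection capacities
#'   for linkers.
#' @return An `esynth_library`.
#' @export
consolidate <- function(fragments,
                        linker_mode = c("saturated", "unsaturated")) {
  linker_mode <- match.arg(linker_mode)
  if (inherits(fragments, "esynth_decomposition")) {
    fragments <- fragments$fragments
  }
  if (inherits(fragments, "esynth_fragment")) fragments <- list(fragments)
  if (length(fragments) == 0L) {
    stop("no fragments to consolidate", call. = FALSE)
  }
  keys <- canonical_keys(lapply(fragments, function(f) f$graph))
  entry_id <- paste0(vapply(fragments, function(f) f$kind, character(1)),
                     ":", keys)
  lib <- structure(list(fragments = list(), linker_mode = linker_mode,
                        provenance = list()),
                   class = "esynth_library")
  for (id in sort(unique(entry_id))) {
    copies <- fragments[entry_id == id]
    lib$fragments[[id]] <- merge_fragment_copies(copies, id)
    lib$provenance[[id]] <-
      sort(unique(unlist(lapply(copies, function(f) f$parents))))
  }
  set_linker_mode(lib, linker_mode)
}

#' @noRd
merge_fragment_copies <- function(copies, id) {
  kind <- copies[[1]]$kind
  key <- sub("^[a-z]+:", "", id)
  canon <- canonical_form(copies[[1]]$graph)
  canon$name <- key
  cls <- symmetry_classes(canon)
  n <- nrow(canon$atoms)
  if (kind == "rigid") {
    class_types <- list()
    for (f in copies) {
      if (!is.list(f$conn)) stop("malformed rigid annotation in ", id,
                                 call. = FALSE)
      r <- canonical_ranks(f$graph)  # rank r[i] = canonical position of atom i
      for (a in names(f$conn)) {
        p <- r[as.integer(a)]
        cl <- cls[p]
        class_types[[cl]] <- sort(unique(c(class_types[[cl]], f$conn[[a]])))
      }
    }
    conn <- stats::setNames(vector("list", 0L), character())
    for (p in seq_len(n)) {
      cl <- cls[p]
      if (!is.null(class_types[[cl]])) {
        conn[[as.character(p)]] <- class_types[[cl]]
      }
    }
    out <- new_fragment("rigid", canon)
    out$conn <- conn
  } else {
    class_orig <- integer(0)
    for (f in copies) {
      if (is.null(f$conn$orig)) stop("malformed linker annotation in ", id,
                                     call. = FALSE)
      r <- canonical_ranks(f$graph)
      po <- integer(n); po[r] <- f$conn$orig
      for (p in seq_len(n)) {
        cl <- cls[p]
        cur <- if (cl %in% names(class_orig)) class_orig[[cl]] else 0L
        class_orig[[cl]] <- max(cur, po[p])
      }
    }
    out <- new_fragment("linker", canon)
    out$conn$orig <- vapply(cls, function(cl) class_orig[[cl]], integer(1),
                            USE.NAMES = FALSE)
    out$conn$sat <- canon$atoms$hcount
  }
  out$parents <- sort(unique(unlist(lapply(copies, function(f) f$parents))))
  out$key <- key
  out
}

#' Switch the linker connection mode of a library
#'
#' In saturated mode every linker atom may form as many bonds as its
#' hydrogen-saturated valence allows; in unsaturated mode it is limited to
#' the connection counts observed in the parent molecules. Rigids are
#' unchanged; toggling twice restores the original counts.
#'
#' @param lib an `esynth_library`.
#' @param mode `"saturated"` or `"unsaturated"`.
#' @return The library with the mode applied.
#' @export
set_linker_mode <- function(lib, mode = c("saturated", "unsaturated")) {
  mode <- match.arg(mode)
  lib$linker_mode <- mode
  for (id in names(lib$fragments)) {
    if (lib$fragments[[id]]$kind == "linker") {
      lib$fragments[[id]]$mode <- mode
    }
  }
  lib
}

#' Active connection counts of a linker fragment
#' @noRd
linker_counts <- function(frag) {
  mode <- if (is.null(frag$mode)) "saturated" else frag$mode
  if (mode == "saturated") frag$conn$sat else
    pmin(frag$conn$orig, frag$conn$sat)
}

#' Maximum number of bonds a linker can form
#'
#' Sum of the per-atom connection counts under the linker's active mode
#' (saturated capacity or original connections).
#'
#' @param linker a linker `esynth_fragment`.
#' @return Integer bond capacity.
#' @export
max_connections <- function(linker) {
  if (!inherits(linker, "esynth_fragment") || linker$kind != "linker") {
    stop("max_connections is defined for linker fragments", call. = FALSE)
  }
  sum(linker_counts(linker))
}

#' @export
print.esynth_library <- function(x, ...) {
  kinds <- vapply(x$fragments, function(f) f$kind, character(1))
  cat(sprintf("<fragment library> %d rigid(s), %d linker(s), %s linkers\n",
              sum(kinds == "rigid"), sum(kinds == "linker"), x$linker_mode))
  invisible(x)
}

#' Number of fragments in a library
#' @param lib an `esynth_library`.
#' @return integer count.
#' @export
library_size <- function(lib) length(lib$fragments)

#' Rigid fragment keys of a library
#' @param lib an `esynth_library`.
#' @return character vector of canonical keys of the rigid entries.
#' @export
rigid_keys <- function(lib) {
  kinds <- vapply(lib$fragments, function(f) f$kind, character(1))
  sort(vapply(lib$fragments[kinds == "rigid"], function(f) f$key,
              character(1)))
}

#' Persist a fragment library as SDF plus JSON index
#'
#' Writes one SDF (with `ESYNTH_*` annotation fields) and a JSON index of
#' keys, kinds, connection annotations and the linker mode.
#'
#' @param lib an `esynth_library`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_library <- function(lib, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  frs <- lib$fragments
  write_molecules(unname(frs), file.path(dir, "fragments.sdf"), "sdf")
  idx <- list(
    linker_mode = lib$linker_mode,
    fragments = lapply(names(frs), function(id) {
      f <- frs[[id]]
      list(id = id, kind = f$kind, key = f$key,
           connections = f$conn, parents = lib$provenance[[id]])
    }))
  jsonlite::write_json(idx, file.path(dir, "index.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(dir)
}

#' Load a fragment library written by [write_library()]
#'
#' @param dir library directory.
#' @return An `esynth_library`.
#' @export
read_library <- function(dir) {
  idx <- jsonlite::read_json(file.path(dir, "index.json"))
  mols <- read_molecules(file.path(dir, "fragments.sdf"), "sdf")
  frs <- fragments_from_molecules(mols)
  lib <- structure(list(fragments = list(), linker_mode = idx$linker_mode,
                        provenance = list()),
                   class = "esynth_library")
  for (k in seq_along(frs)) {
    meta <- idx$fragments[[k]]
    f <- frs[[k]]
    f$key <- meta$key
    lib$fragments[[meta$id]] <- f
    lib$provenance[[meta$id]] <- unlist(meta$parents)
  }
  set_linker_mode(lib, idx$linker_mode)
}
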