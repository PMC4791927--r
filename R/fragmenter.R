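# Decomposition of parent molecules into rigid fragments and flexible
# linkers. Rigids are connected sets of >= 4 heavy atoms joined by
# non-rotatable bonds; everything else is linker material, with adjacent
# linker pieces re-merged into longer linkers. Severed bonds are recorded as
# junctions carrying the connectivity information used later by synthesis.

#' Find rotatable bonds
#'
#' A bond is rotatable when it is a single bond not in a ring, both end atoms
#' have at least two heavy-atom neighbours (severing next to a terminal atom
#' would not create a torsion), and it is not an amide C(=O)-N bond. This is
#' the torsion convention of AutoDock-family ligand preparation.
#'
#' @param mol a typed `molecule_graph`.
#' @return data.frame with columns `i`, `j` (one row per rotatable bond,
#'   i < j, sorted).
#' @export
find_rotatable_bonds <- function(mol) {
  b <- mol$bonds
  empty <- data.frame(i = integer(), j = integer())
  if (nrow(b) == 0L) return(empty)
  g <- graph_of(mol)
  bridge_eids <- igraph::bridges(g)
  in_ring <- rep(TRUE, nrow(b))
  in_ring[as.integer(bridge_eids)] <- FALSE
  deg <- tabulate(c(b$i, b$j), nbins = nrow(mol$atoms))
  el <- mol$atoms$element
  dbl_o <- logical(nrow(mol$atoms))  # carbon with a double bond to oxygen
  for (k in seq_len(nrow(b))) {
    if (b$order[k] == 2L) {
      if (el[b$i[k]] == "C" && el[b$j[k]] == "O") dbl_o[b$i[k]] <- TRUE
      if (el[b$j[k]] == "C" && el[b$i[k]] == "O") dbl_o[b$j[k]] <- TRUE
    }
  }
  rot <- vapply(seq_len(nrow(b)), function(k) {
    i <- b$i[k]; j <- b$j[k]
    if (b$order[k] != 1L || in_ring[k]) return(FALSE)
    if (deg[i] < 2L || deg[j] < 2L) return(FALSE)
    amide <- (el[i] == "C" && dbl_o[i] && el[j] == "N") ||
             (el[j] == "C" && dbl_o[j] && el[i] == "N")
    !amide
  }, logical(1))
  out <- data.frame(i = pmin(b$i[rot], b$j[rot]),
                    j = pmax(b$i[rot], b$j[rot]))
  out[order(out$i, out$j), , drop = FALSE]
}

#' Decompose a molecule into rigid fragments and linkers
#'
#' Rotatable bonds are severed; connected components with at least
#' `min_rigid_atoms` heavy atoms become rigid fragments, everything else
#' becomes linker material, and linker pieces adjacent through a severed bond
#' are re-merged (the severed bond restored) into one longer linker. All
#' fragments are hydrogen-saturated at the severed positions and keep their
#' parent SYBYL types; each severed rigid-rigid or rigid-linker bond is
#' recorded as a junction. Connection annotations are filled by
#' [annotate_connections()], which [decompose()] calls by default.
#'
#' @param mol a typed `molecule_graph` with at least one heavy atom.
#' @param min_rigid_atoms minimum heavy-atom count of a rigid fragment.
#' @param annotate also run [annotate_connections()].
#' @return An `esynth_decomposition`: list with `fragments` (named list of
#'   `esynth_fragment`, ids R1.., L1..), `junctions` (data.frame `frag_a`,
#'   `atom_a`, `frag_b`, `atom_b`, local atom indices) and `parent`.
#' @export
decompose <- function(mol, min_rigid_atoms = 4L, annotate = TRUE) {
  if (nrow(mol$atoms) < 1L) stop("empty molecule", call. = FALSE)
  rb <- find_rotatable_bonds(mol)
  b <- mol$bonds
  bkey <- paste(pmin(b$i, b$j), pmax(b$i, b$j))
  is_rot <- bkey %in% paste(rb$i, rb$j)

  # pass 1: classify components of the fully severed graph
  comp1 <- bond_components(nrow(mol$atoms), b[!is_rot, , drop = FALSE])
  sizes <- tabulate(comp1)
  rigid_comp <- which(sizes >= min_rigid_atoms)
  atom_is_rigid <- comp1 %in% rigid_comp

  # pass 2: restore severed bonds between two linker components
  restore <- is_rot & !atom_is_rigid[b$i] & !atom_is_rigid[b$j]
  keep <- !is_rot | restore
  comp2 <- bond_components(nrow(mol$atoms), b[keep, , drop = FALSE])

  comp_ids <- sort(unique(comp2))
  frag_of_atom <- integer(nrow(mol$atoms))
  frags <- list()
  locals <- vector("list", length(comp_ids))
  kinds <- character(length(comp_ids))
  for (ci in seq_along(comp_ids)) {
    atoms <- which(comp2 == comp_ids[ci])
    kinds[ci] <- if (all(atom_is_rigid[atoms])) "rigid" else "linker"
    frag_of_atom[atoms] <- ci
    locals[[ci]] <- atoms
  }
  ord <- order(kinds != "rigid", vapply(locals, min, integer(1)))
  ids <- character(length(comp_ids))
  nr <- 0L; nl <- 0L
  for (ci in ord) {
    if (kinds[ci] == "rigid") { nr <- nr + 1L; ids[ci] <- paste0("R", nr) }
    else { nl <- nl + 1L; ids[ci] <- paste0("L", nl) }
  }
  for (ci in seq_along(comp_ids)) {
    sub <- subgraph_mol(mol, locals[[ci]],
                        name = paste0(mol$name, ":", ids[ci]))
    sub <- fill_hydrogen_counts(sub)
    frags[[ids[ci]]] <- new_fragment(kinds[ci], sub, parents = mol$name)
  }
  frags <- frags[order(names(frags))]

  sever <- which(is_rot & !restore)
  junctions <- data.frame(frag_a = character(), atom_a = integer(),
                          frag_b = character(), atom_b = integer(),
                          stringsAsFactors = FALSE)
  for (k in sever) {
    ca <- frag_of_atom[b$i[k]]; cb <- frag_of_atom[b$j[k]]
    junctions <- rbind(junctions, data.frame(
      frag_a = ids[ca], atom_a = match(b$i[k], locals[[ca]]),
      frag_b = ids[cb], atom_b = match(b$j[k], locals[[cb]]),
      stringsAsFactors = FALSE))
  }
  dec <- structure(list(fragments = frags, junctions = junctions,
                        parent = mol),
                   class = "esynth_decomposition")
  if (annotate) annotate_connections(dec) else dec
}

#' @noRd
bond_components <- function(n, bonds) {
  g <- igraph::graph_from_data_frame(
    d = if (nrow(bonds)) bonds[, c("i", "j")] else
      data.frame(i = integer(), j = integer()),
    directed = FALSE, vertices = data.frame(name = seq_len(n)))
  as.integer(igraph::components(g)$membership)
}

#' @export
print.esynth_decomposition <- function(x, ...) {
  kinds <- vapply(x$fragments, function(f) f$kind, character(1))
  cat(sprintf("<decomposition> %s: %d rigid(s), %d linker(s), %d junction(s)\n",
              x$parent$name, sum(kinds == "rigid"), sum(kinds == "linker"),
              nrow(x$junctions)))
  invisible(x)
}

#' Construct a fragment object
#'
#' @param kind `"rigid"` or `"linker"`.
#' @param graph hydrogen-saturated `molecule_graph` carrying parent SYBYL
#'   types.
#' @param parents parent molecule names (provenance).
#' @return An `esynth_fragment`: rigid connections map attachment atoms to the
#'   sets of partner SYBYL types observed at severed bonds; linker connections
#'   hold per-atom original counts (`orig`) and saturated hydrogen capacities
#'   (`sat`).
#' @export
new_fragment <- function(kind = c("rigid", "linker"), graph,
                         parents = character()) {
  kind <- match.arg(kind)
  n <- nrow(graph$atoms)
  conn <- if (kind == "rigid") {
    stats::setNames(vector("list", 0L), character())
  } else {
    list(orig = integer(n), sat = graph$atoms$hcount)
  }
  structure(list(kind = kind, graph = graph, conn = conn,
                 parents = unique(parents), key = NULL),
            class = "esynth_fragment")
}

#' @export
print.esynth_fragment <- function(x, ...) {
  cat(sprintf("<%s fragment> %s: %d heavy atoms\n", x$kind, x$graph$name,
              nrow(x$graph$atoms)))
  invisible(x)
}

#' Canonical key of a fragment
#' @param frag an `esynth_fragment`.
#' @return Canonical SMILES of the saturated fragment graph (connection
#'   annotations excluded from identity).
#' @export
fragment_key <- function(frag) {
  if (is.null(frag$key)) canonical_key(frag$graph) else frag$key
}

#' Annotate fragment connectivity from recorded junctions
#'
#' Each rigid attachment atom accumulates the SYBYL types of its original
#' partner atoms across all junctions; each linker atom accumulates its
#' original connection count. Saturated linker capacities are the hydrogen
#' counts of the saturated atoms and are recorded at saturation time.
#'
#' @param dec an `esynth_decomposition`.
#' @return The decomposition with fragment connection annotations filled.
#' @export
annotate_connections <- function(dec) {
  j <- dec$junctions
  for (k in seq_len(nrow(j))) {
    sides <- list(list(f = j$frag_a[k], a = j$atom_a[k],
                       pf = j$frag_b[k], pa = j$atom_b[k]),
                  list(f = j$frag_b[k], a = j$atom_b[k],
                       pf = j$frag_a[k], pa = j$atom_a[k]))
    for (s in sides) {
      frag <- dec$fragments[[s$f]]
      if (is.null(frag)) stop("junction references unknown fragment ", s$f,
                              call. = FALSE)
      if (s$a < 1L || s$a > nrow(frag$graph$atoms)) {
        stop("junction references unknown atom ", s$a, " of ", s$f,
             call. = FALSE)
      }
      partner_type <- dec$fragments[[s$pf]]$graph$atoms$sybyl[s$pa]
      if (frag$kind == "rigid") {
        key <- as.character(s$a)
        frag$conn[[key]] <- sort(unique(c(frag$conn[[key]], partner_type)))
      } else {
        frag$conn$orig[s$a] <- frag$conn$orig[s$a] + 1L
      }
      dec$fragments[[s$f]] <- frag
    }
  }
  dec
}

#' Saturate a fragment with hydrogens
#'
#' Raises each atom's hydrogen count so its total valence is satisfied; the
#' heavy-atom graph is unchanged and the operation is idempotent. Saturated
#' linker capacities (`conn$sat`) are refreshed to the new hydrogen counts.
#'
#' @param frag an `esynth_fragment`.
#' @return The saturated fragment.
#' @export
saturate_with_hydrogens <- function(frag) {
  frag$graph <- fill_hydrogen_counts(frag$graph)
  if (frag$kind == "linker") frag$conn$sat <- frag$graph$atoms$hcount
  frag
}

#' @noRd
fragment_sdf_fields <- function(x) {
  if (!inherits(x, "esynth_fragment")) {
    f <- attr(x, "sdf_fields")
    return(if (length(f)) vapply(f, paste, character(1), collapse = " ") else
             NULL)
  }
  conn_lines <- if (x$kind == "rigid") {
    vapply(names(x$conn), function(a) {
      sprintf("%s types=%s", a, paste(x$conn[[a]], collapse = ","))
    }, character(1))
  } else {
    idx <- which(x$conn$orig > 0L | x$conn$sat > 0L)
    vapply(idx, function(a) {
      sprintf("%d orig=%d max=%d", a, x$conn$orig[a], x$conn$sat[a])
    }, character(1))
  }
  if (length(conn_lines) == 0L) conn_lines <- "none"
  c(ESYNTH_KIND = x$kind,
    ESYNTH_CONNECTIONS = paste(conn_lines, collapse = "\n"),
    ESYNTH_PARENTS = paste(x$parents, collapse = " "))
}

#' Rebuild fragment objects from annotated graphs
#'
#' Inverse of the `ESYNTH_*` SDF serialization written by [write_molecules()].
#'
#' @param mols list of `molecule_graph`s carrying `sdf_fields` attributes.
#' @return List of `esynth_fragment` objects.
#' @export
fragments_from_molecules <- function(mols) {
  lapply(mols, function(m) {
    f <- attr(m, "sdf_fields")
    kind <- if (!is.null(f$ESYNTH_KIND)) f$ESYNTH_KIND[1] else "rigid"
    parents <- if (!is.null(f$ESYNTH_PARENTS))
      strsplit(f$ESYNTH_PARENTS[1], " ", fixed = TRUE)[[1]] else character()
    frag <- new_fragment(kind, fill_hydrogen_counts(m), parents = parents)
    lines <- f$ESYNTH_CONNECTIONS
    lines <- lines[!is.null(lines) & lines != "none"]
    for (ln in lines) {
      parts <- strsplit(trimws(ln), " ", fixed = TRUE)[[1]]
      a <- as.integer(parts[1])
      if (kind == "rigid") {
        frag$conn[[as.character(a)]] <-
          sort(strsplit(sub("^types=", "", parts[2]), ",")[[1]])
      } else {
        frag$conn$orig[a] <- as.integer(sub("^orig=", "", parts[2]))
        frag$conn$sat[a] <- as.integer(sub("^max=", "", parts[3]))
      }
    }
    frag
  })
}
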