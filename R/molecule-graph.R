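#' Molecular graph
#'
#' A typed heavy-atom graph: atoms carry element, SYBYL type, formal charge,
#' implicit hydrogen count and optional 3D coordinates; bonds carry integer
#' orders (1, 2, 3). Hydrogens are counted, never instantiated as nodes. Atom
#' indices are row numbers of the atom table.
#'
#' @param atoms data.frame with columns `element`, `sybyl` (may be NA before
#'   typing), `charge`, `hcount` (may be NA; filled by
#'   [fill_hydrogen_counts()]), and optionally `x`, `y`, `z`.
#' @param bonds data.frame with columns `i`, `j`, `order` (integer 1-3).
#' @param name molecule title.
#' @param validate run structural checks (connectivity, duplicate bonds).
#' @return An object of class `molecule_graph`.
#' @export
molecule_graph <- function(atoms, bonds, name = "", validate = TRUE) {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  if (!all(c("element", "charge") %in% names(atoms))) {
    stop("atoms needs at least element and charge columns", call. = FALSE)
  }
  if (is.null(atoms$sybyl)) atoms$sybyl <- rep(NA_character_, nrow(atoms))
  if (is.null(atoms$hcount)) atoms$hcount <- rep(NA_integer_, nrow(atoms))
  for (cc in c("x", "y", "z")) {
    if (is.null(atoms[[cc]])) atoms[[cc]] <- rep(0, nrow(atoms))
  }
  rownames(atoms) <- NULL
  if (nrow(bonds) > 0L) {
    bonds <- data.frame(i = as.integer(bonds$i), j = as.integer(bonds$j),
                        order = as.integer(bonds$order))
  } else {
    bonds <- data.frame(i = integer(), j = integer(), order = integer())
  }
  mol <- structure(list(atoms = atoms, bonds = bonds, name = as.character(name)),
                   class = "molecule_graph")
  if (validate) validate_molecule_graph(mol)
  mol
}

#' Number of heavy atoms in a molecular graph
#' @param mol a `molecule_graph`.
#' @return integer atom count.
#' @export
n_atoms <- function(mol) nrow(mol$atoms)

#' @export
print.molecule_graph <- function(x, ...) {
  cat(sprintf("<molecule_graph> %s: %d heavy atoms, %d bonds\n",
              if (nzchar(x$name)) x$name else "(unnamed)",
              nrow(x$atoms), nrow(x$bonds)))
  invisible(x)
}

#' Validate the structural invariants of a molecular graph
#'
#' Checks that the graph is connected, has no self-bonds or duplicate bonds,
#' references only existing atoms, and (when hydrogen counts are present) that
#' each atom's total valence is an allowed valence of its element.
#'
#' @param mol a `molecule_graph`.
#' @return `mol`, invisibly; errors on violation.
#' @export
validate_molecule_graph <- function(mol) {
  n <- nrow(mol$atoms)
  if (n < 1L) stop("molecule has no atoms", call. = FALSE)
  b <- mol$bonds
  if (nrow(b) > 0L) {
    if (any(b$i < 1L | b$i > n | b$j < 1L | b$j > n)) {
      stop("bond references unknown atom", call. = FALSE)
    }
    if (any(b$i == b$j)) stop("self-bond found", call. = FALSE)
    key <- paste(pmin(b$i, b$j), pmax(b$i, b$j))
    if (anyDuplicated(key)) stop("duplicate bond found", call. = FALSE)
    if (any(!b$order %in% 1:3)) {
      stop("bond orders must be 1, 2 or 3 (Kekule form)", call. = FALSE)
    }
  }
  if (n > 1L) {
    g <- graph_of(mol)
    if (igraph::components(g)$no != 1L) {
      stop("molecular graph is not connected", call. = FALSE)
    }
  }
  if (!anyNA(mol$atoms$hcount)) {
    bs <- bond_order_sums(mol)
    for (i in seq_len(n)) {
      el <- mol$atoms$element[i]
      vals <- .ELEMENT_VALENCES[[el]]
      if (is.null(vals)) stop("unsupported element: ", el, call. = FALSE)
      vals <- vals + as.integer(mol$atoms$charge[i]) *
        switch(el, N = 1L, O = 1L, 0L)
      tot <- bs[i] + mol$atoms$hcount[i]
      if (!tot %in% vals) {
        stop(sprintf("atom %d (%s) has total valence %d, allowed: %s",
                     i, el, tot, paste(vals, collapse = "/")), call. = FALSE)
      }
    }
  }
  invisible(mol)
}

#' @noRd
graph_of <- function(mol) {
  igraph::graph_from_data_frame(
    d = if (nrow(mol$bonds)) mol$bonds[, c("i", "j")] else
      data.frame(i = integer(), j = integer()),
    directed = FALSE,
    vertices = data.frame(name = seq_len(nrow(mol$atoms))))
}

#' @noRd
bond_order_sums <- function(mol) {
  bs <- numeric(nrow(mol$atoms))
  if (nrow(mol$bonds)) {
    t1 <- tapply(mol$bonds$order, mol$bonds$i, sum)
    t2 <- tapply(mol$bonds$order, mol$bonds$j, sum)
    bs[as.integer(names(t1))] <- bs[as.integer(names(t1))] + t1
    bs[as.integer(names(t2))] <- bs[as.integer(names(t2))] + t2
  }
  as.integer(bs)
}

#' Fill implicit hydrogen counts from the valence model
#'
#' Sets each atom's hydrogen count to its element's (charge-adjusted) valence
#' minus the sum of its heavy-atom bond orders. On a fragment cut out of a
#' parent molecule this saturates the severed positions with hydrogens while
#' leaving the heavy-atom graph untouched; on an already saturated molecule it
#' is the identity.
#'
#' @param mol a `molecule_graph`.
#' @return `mol` with `hcount` filled.
#' @export
fill_hydrogen_counts <- function(mol) {
  bs <- bond_order_sums(mol)
  mol$atoms$hcount <- vapply(seq_len(nrow(mol$atoms)), function(i) {
    implicit_hydrogens(mol$atoms$element[i], mol$atoms$charge[i], bs[i])
  }, integer(1))
  mol
}

#' Heavy-atom neighbour lists
#' @noRd
neighbor_list <- function(mol) {
  n <- nrow(mol$atoms)
  nb <- vector("list", n)
  b <- mol$bonds
  for (k in seq_len(nrow(b))) {
    nb[[b$i[k]]] <- c(nb[[b$i[k]]], b$j[k])
    nb[[b$j[k]]] <- c(nb[[b$j[k]]], b$i[k])
  }
  nb
}

#' Extract the induced subgraph on a set of atoms
#'
#' Keeps the listed atoms (renumbered 1..k in the order given) and all bonds
#' between them.
#' @noRd
subgraph_mol <- function(mol, keep, name = mol$name) {
  keep <- as.integer(keep)
  map <- integer(nrow(mol$atoms))
  map[keep] <- seq_along(keep)
  b <- mol$bonds
  sel <- b$i %in% keep & b$j %in% keep
  nb <- b[sel, , drop = FALSE]
  nb$i <- map[nb$i]; nb$j <- map[nb$j]
  molecule_graph(mol$atoms[keep, , drop = FALSE], nb, name = name,
                 validate = FALSE)
}

#' Exact molecular weight of a molecular graph
#'
#' Sum of standard atomic weights over heavy atoms plus 1.008 Da per counted
#' hydrogen.
#'
#' @param mol a `molecule_graph` with hydrogen counts filled.
#' @return Molecular weight in Daltons.
#' @export
molecular_weight <- function(mol) {
  if (anyNA(mol$atoms$hcount)) stop("hydrogen counts not filled", call. = FALSE)
  sum(.ATOMIC_WEIGHTS[mol$atoms$element]) +
    .ATOMIC_WEIGHTS[["H"]] * sum(mol$atoms$hcount)
}

#' Permute the atom order of a molecular graph
#'
#' Relabels atoms by a permutation (the atom at old index `perm[k]` becomes
#' atom `k`). Used by canonicalization stress tests; the canonical key must be
#' invariant under any such relabeling.
#'
#' @param mol a `molecule_graph`.
#' @param perm a permutation of `seq_len(n_atoms(mol))`.
#' @return The relabeled `molecule_graph`.
#' @export
permute_atoms <- function(mol, perm) {
  stopifnot(length(perm) == nrow(mol$atoms), !anyDuplicated(perm))
  inv <- integer(length(perm))
  inv[perm] <- seq_along(perm)
  b <- mol$bonds
  b$i <- inv[b$i]; b$j <- inv[b$j]
  molecule_graph(mol$atoms[perm, , drop = FALSE], b, name = mol$name,
                 validate = FALSE)
}
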