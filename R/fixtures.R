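# Deterministic synthetic fixture generation: multi-fragment parent
# molecules assembled from a known panel of rigids and linkers, with known
# decompositions, so the benchmarking protocols can run without any external
# compound database. Parents alternate rigid and linker fragments along a
# chain, are Rule-of-Five compliant (modified cutoffs) both exactly and in
# their fragment-additive estimates, and decompose back to exactly the
# fragment multiset they were assembled from.

#' Default fragment panel for fixture generation
#'
#' Four aromatic rigids (benzene, pyridine, thiophene, 2,5-dimethylfuran)
#' and five linkers (methylene bridge, two-carbon chain, the three-atom
#' C-C-N chain, carboxylic acid, sulfonamide).
#'
#' @return list with `rigids` and `linkers`, each a list of
#'   `esynth_fragment`s.
#' @export
default_fragment_panel <- function() {
  rigid <- function(smi, name) {
    new_fragment("rigid", smiles_to_molecule(smi, name))
  }
  linker <- function(smi, name) {
    new_fragment("linker", smiles_to_molecule(smi, name))
  }
  list(
    rigids = list(rigid("c1ccccc1", "benzene"),
                  rigid("c1ccncc1", "pyridine"),
                  rigid("c1ccsc1", "thiophene"),
                  rigid("Cc1ccc(C)o1", "dimethylfuran")),
    linkers = list(linker("C", "methylene"),
                   linker("CC", "ethylene"),
                   linker("CCN", "aminoethyl"),
                   linker("OC=O", "carboxyl"),
                   linker("NS(=O)=O", "sulfonamide")))
}

#' Generate a deterministic panel of synthetic parent molecules
#'
#' Assembles `n_parents` molecules of 2-6 fragments each by alternately
#' bonding rigid and linker fragments along a chain (single-atom linkers
#' only in bridging positions, so every severed bond is a genuine torsion).
#' Each parent is checked to (a) decompose back to exactly its generating
#' fragment multiset and (b) pass the modified Rule-of-Five both on exact
#' descriptors and on the fragment-additive estimate; failing draws are
#' rejected and redrawn. The same seed always yields the same panel.
#'
#' @param seed RNG seed.
#' @param n_parents number of parents to generate.
#' @param fragment_panel panel from [default_fragment_panel()].
#' @return List of typed `molecule_graph`s; each carries attributes
#'   `fragment_keys` (sorted canonical keys of its generating fragments) and
#'   `n_fragments`.
#' @export
make_fixtures <- function(seed = 42L, n_parents = 10L,
                          fragment_panel = default_fragment_panel()) {
  if (length(fragment_panel$rigids) == 0L ||
      length(fragment_panel$linkers) == 0L) {
    stop("fragment panel needs at least one rigid and one linker",
         call. = FALSE)
  }
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  rkeys <- canonical_keys(lapply(fragment_panel$rigids, function(f) f$graph))
  lkeys <- canonical_keys(lapply(fragment_panel$linkers, function(f) f$graph))
  lsize <- vapply(fragment_panel$linkers,
                  function(f) nrow(f$graph$atoms), integer(1))
  out <- vector("list", n_parents)
  thr <- ro5_thresholds("modified")
  for (p in seq_len(n_parents)) {
    parent <- NULL
    for (attempt in 1:200) {
      k <- sample(2:6, 1L)
      built <- try(assemble_chain(k, fragment_panel, lsize), silent = TRUE)
      if (inherits(built, "try-error")) next
      name <- sprintf("fixture%02d", p)
      g <- built$graph
      g$name <- name
      g <- tryCatch(assign_sybyl_types(fill_hydrogen_counts(g)),
                    error = function(e) NULL)
      if (is.null(g)) next
      used_keys <- sort(c(rkeys[built$rigid_idx], lkeys[built$linker_idx]))
      used_tag <- sort(c(paste("rigid", rkeys[built$rigid_idx]),
                         paste("linker", lkeys[built$linker_idx])))
      dec <- decompose(g)
      got_keys <- canonical_keys(lapply(dec$fragments, function(f) f$graph))
      got_tag <- sort(paste(vapply(dec$fragments, function(f) f$kind,
                                   character(1)), got_keys))
      if (!identical(got_tag, used_tag)) next
      ex <- lipinski_descriptors(g)
      raw <- colSums(lipinski_descriptors(
        lapply(dec$fragments, function(f) f$graph)))
      if (!passes_ro5(ex, thr, "final")) next
      if (!(raw[["MW"]] <= thr$max_MW && raw[["HBD"]] <= thr$max_HBD &&
            raw[["HBA"]] <= thr$max_HBA)) next
      attr(g, "fragment_keys") <- used_keys
      attr(g, "n_fragments") <- k
      parent <- g
      break
    }
    if (is.null(parent)) {
      stop("could not assemble a valid parent from the fragment panel",
           call. = FALSE)
    }
    out[[p]] <- parent
  }
  out
}

#' @noRd
assemble_chain <- function(k, panel, lsize) {
  kinds <- rep(c("rigid", "linker"), length.out = k)
  ridx <- integer(0); lidx <- integer(0)
  pick_rigid <- function() sample(length(panel$rigids), 1L)
  pick_linker <- function(terminal) {
    ok <- if (terminal) which(lsize >= 2L) else seq_along(lsize)
    ok[sample(length(ok), 1L)]
  }
  i0 <- pick_rigid()
  ridx <- i0
  g <- panel$rigids[[i0]]$graph
  prev <- seq_len(nrow(g$atoms))
  prev_kind <- "rigid"
  for (pos in seq(2L, k)) {
    kind <- kinds[pos]
    terminal <- pos == k
    if (kind == "rigid") { fi <- pick_rigid(); frag <- panel$rigids[[fi]] }
    else { fi <- pick_linker(terminal); frag <- panel$linkers[[fi]] }
    fg <- frag$graph
    # junction atom on the previous fragment
    acand <- if (prev_kind == "rigid") {
      prev[g$atoms$sybyl[prev] == "C.ar" & g$atoms$hcount[prev] >= 1L]
    } else {
      prev[g$atoms$hcount[prev] >= 1L]
    }
    if (length(acand) == 0L) stop("no junction atom available")
    a <- acand[sample(length(acand), 1L)]
    # junction atom on the incoming fragment
    bcand <- if (kind == "rigid") {
      which(fg$atoms$sybyl == "C.ar" & fg$atoms$hcount >= 1L)
    } else {
      which(fg$atoms$hcount >= 1L)
    }
    if (length(bcand) == 0L) stop("no junction atom on fragment")
    b <- bcand[sample(length(bcand), 1L)]
    n1 <- nrow(g$atoms)
    fb <- fg$bonds; fb$i <- fb$i + n1; fb$j <- fb$j + n1
    g$atoms <- rbind(g$atoms, fg$atoms)
    rownames(g$atoms) <- NULL
    g$bonds <- rbind(g$bonds, fb,
                     data.frame(i = a, j = b + n1, order = 1L))
    g$atoms$hcount[a] <- g$atoms$hcount[a] - 1L
    g$atoms$hcount[b + n1] <- g$atoms$hcount[b + n1] - 1L
    if (kind == "rigid") ridx <- c(ridx, fi) else lidx <- c(lidx, fi)
    prev <- n1 + seq_len(nrow(fg$atoms))
    prev_kind <- kind
  }
  list(graph = g, rigid_idx = ridx, linker_idx = lidx)
}
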