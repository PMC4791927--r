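# Chemical similarity: Tanimoto over hashed FP2 fingerprints (1D-TC),
# Tanimoto over a maximum common connected substructure atom mapping
# (2D-TC), and greedy leader clustering at a TC threshold.

#' Fingerprint Tanimoto coefficient (1D-TC)
#'
#' Tanimoto similarity of hashed path-based (FP2) fingerprints. A value of
#' 1.0 denotes identical fingerprints, not necessarily identical structures.
#' Molecules too small to set any fingerprint bit compare as 1 against each
#' other.
#'
#' @param a,b `molecule_graph` objects.
#' @return similarity in \[0, 1\].
#' @export
fingerprint_tc <- function(a, b) {
  fp <- fingerprint_matrix(list(a, b)) > 0
  tanimoto_rows(fp)[1, 2]
}

#' Pairwise fingerprint Tanimoto matrix
#'
#' @param mols list of `molecule_graph`s.
#' @return symmetric matrix of 1D-TC values.
#' @export
tanimoto_matrix <- function(mols) {
  fp <- fingerprint_matrix(mols) > 0
  tanimoto_rows(fp)
}

#' Fingerprint Tanimoto of one target against a set
#'
#' @param target a `molecule_graph`.
#' @param mols list of `molecule_graph`s.
#' @return numeric vector of 1D-TC values, one per molecule in `mols`.
#' @export
tanimoto_to <- function(target, mols) {
  fp <- fingerprint_matrix(c(list(target), mols)) > 0
  t1 <- fp[1, ]
  common <- as.numeric(fp[-1, , drop = FALSE] %*% t1)
  sizes <- rowSums(fp[-1, , drop = FALSE])
  denom <- sizes + sum(t1) - common
  ifelse(denom > 0, common / denom, 1)
}

#' @noRd
tanimoto_rows <- function(fp) {
  fp <- fp * 1L
  common <- fp %*% t(fp)
  sizes <- diag(common)
  denom <- outer(sizes, sizes, `+`) - common
  tc <- ifelse(denom > 0, common / denom, 1)
  tc
}

#' Maximum-common-substructure Tanimoto coefficient (2D-TC)
#'
#' Finds a maximum common connected substructure between two molecules by
#' backtracking search with SYBYL-type-equal atom matching and
#' adjacency-preserving extension, then scores
#' `|MCS| / (|a| + |b| - |MCS|)` over heavy atoms. The search is exact up to
#' the time budget; on timeout NA is returned rather than an underestimate.
#'
#' @param a,b `molecule_graph` objects.
#' @param time_budget seconds allowed for the search.
#' @return similarity in \[0, 1\], or NA on timeout.
#' @export
mcs_tc <- function(a, b, time_budget = 5) {
  na <- nrow(a$atoms); nb <- nrow(b$atoms)
  size <- mcs_size(a, b, time_budget)
  if (is.na(size)) return(NA_real_)
  size / (na + nb - size)
}

#' @noRd
mcs_size <- function(a, b, time_budget = 5) {
  ta <- a$atoms$sybyl; tb <- b$atoms$sybyl
  nba <- neighbor_list(a); nbb <- neighbor_list(b)
  na <- length(ta); nb <- length(tb)
  adja <- matrix(FALSE, na, na); adjb <- matrix(FALSE, nb, nb)
  for (k in seq_len(nrow(a$bonds))) {
    adja[a$bonds$i[k], a$bonds$j[k]] <- TRUE
    adja[a$bonds$j[k], a$bonds$i[k]] <- TRUE
  }
  for (k in seq_len(nrow(b$bonds))) {
    adjb[b$bonds$i[k], b$bonds$j[k]] <- TRUE
    adjb[b$bonds$j[k], b$bonds$i[k]] <- TRUE
  }
  deadline <- Sys.time() + time_budget
  best <- 0L
  timed_out <- FALSE

  # Branch on the smallest frontier atom u of a: either map u onto one of
  # the compatible frontier atoms of b, or exclude u from the mapping.
  extend <- function(mapA, mapB, excluded) {
    if (timed_out) return()
    if (Sys.time() > deadline) { timed_out <<- TRUE; return() }
    n <- length(mapA)
    if (n > best) best <<- n
    if (n + min(na - n - length(excluded), nb - n) <= best) return()
    frontier <- setdiff(unique(unlist(nba[mapA])), c(mapA, excluded))
    if (length(frontier) == 0L) return()
    u <- min(frontier)
    cand_v <- setdiff(unique(unlist(nbb[mapB])), mapB)
    for (v in cand_v) {
      if (ta[u] != tb[v]) next
      ok <- TRUE
      for (t in seq_len(n)) {
        if (adja[u, mapA[t]] != adjb[v, mapB[t]]) { ok <- FALSE; break }
      }
      if (!ok) next
      extend(c(mapA, u), c(mapB, v), excluded)
      if (timed_out) return()
    }
    extend(mapA, mapB, c(excluded, u))
  }

  for (u in seq_len(na)) {
    for (v in seq_len(nb)) {
      if (ta[u] != tb[v]) next
      extend(u, v, integer(0))
      if (timed_out) break
    }
    if (best == min(na, nb) || timed_out) break
  }
  if (timed_out && best < min(na, nb)) return(NA_integer_)
  best
}

#' Greedy leader clustering at a Tanimoto threshold
#'
#' Compounds are visited in sorted-canonical-key order; each is assigned to
#' the first cluster whose representative (its founding compound) has 1D-TC
#' at or above the threshold, otherwise it founds a new cluster. The result
#' partitions the input and is deterministic.
#'
#' @param mols list of `molecule_graph`s.
#' @param threshold TC similarity threshold (default 0.7).
#' @return An `esynth_clusters`: list with `clusters` (list of integer index
#'   vectors into `mols`), `representatives`, `threshold`, `keys`.
#' @export
cluster_compounds <- function(mols, threshold = 0.7) {
  if (length(mols) == 0L) stop("no compounds to cluster", call. = FALSE)
  keys <- canonical_keys(mols)
  ord <- order(keys)
  tc <- tanimoto_matrix(mols)
  reps <- integer(0)
  clusters <- list()
  for (i in ord) {
    placed <- FALSE
    for (ci in seq_along(reps)) {
      if (tc[i, reps[ci]] >= threshold) {
        clusters[[ci]] <- c(clusters[[ci]], i)
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      reps <- c(reps, i)
      clusters[[length(clusters) + 1L]] <- i
    }
  }
  structure(list(clusters = clusters, representatives = reps,
                 threshold = threshold, keys = keys),
            class = "esynth_clusters")
}

#' @export
print.esynth_clusters <- function(x, ...) {
  cat(sprintf("<clusters> %d compound(s) in %d cluster(s) at TC >= %g\n",
              length(x$keys), length(x$clusters), x$threshold))
  invisible(x)
}
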