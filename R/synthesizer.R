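# The synthesis engine. A k-molecule is a molecule composed of k fragment
# instances; Compose joins two partial molecules by one new single bond in
# every orientation permitted by the connectivity annotations (rigid
# attachment atoms accept listed partner SYBYL types while they still carry
# hydrogens; linker atoms carry explicit remaining connection counts;
# linker-linker bonds are prohibited). Exhaustive synthesis builds level
# k from level k-1 by attaching single fragments, completing each level
# before the next; the bounded variant adds per-level worklist capacities,
# Bloom-filter deduplication and the pre-synthesis drug-likeness gate.

#' Synthesis configuration
#'
#' @param max_level maximum number of fragments per molecule (MAX, >= 2).
#' @param level_capacity per-level worklist bound for [synthesize_bounded()].
#' @param wall_time_limit wall-clock budget in seconds for the bounded
#'   variant (default 1 h).
#' @param linker_mode `"saturated"` or `"unsaturated"`; applied to the
#'   library before synthesis.
#' @param prefilter gate intermediates on estimated MW/HBD/HBA (logP is only
#'   used in final filtering).
#' @param final_filter also drop output molecules failing the full
#'   Rule-of-Five (including logP) on exact descriptors.
#' @param thresholds a [ro5_thresholds()] list.
#' @param calibration optional `esynth_calibration` applied to estimates
#'   before gating.
#' @param bloom_n,bloom_p Bloom filter capacity and false-positive design
#'   rate per filter (bounded variant).
#' @param verbose log per-level progress (generated / gate-rejected /
#'   duplicate-rejected / accepted counts) to stderr.
#' @return A `synthesis_config` list.
#' @export
synthesis_config <- function(max_level = 4L, level_capacity = Inf,
                             wall_time_limit = 3600,
                             linker_mode = c("saturated", "unsaturated"),
                             prefilter = TRUE, final_filter = FALSE,
                             thresholds = ro5_thresholds("modified"),
                             calibration = NULL,
                             bloom_n = 1e7, bloom_p = 0.01,
                             verbose = FALSE) {
  linker_mode <- match.arg(linker_mode)
  if (max_level < 2L) stop("max_level must be >= 2", call. = FALSE)
  if (level_capacity < 1) stop("level_capacity must be >= 1", call. = FALSE)
  structure(list(max_level = as.integer(max_level),
                 level_capacity = level_capacity,
                 wall_time_limit = wall_time_limit,
                 linker_mode = linker_mode,
                 prefilter = prefilter, final_filter = final_filter,
                 thresholds = thresholds, calibration = calibration,
                 bloom_n = bloom_n, bloom_p = bloom_p, verbose = verbose),
            class = "synthesis_config")
}

#' Turn a library fragment into a 1-molecule synthesis state
#'
#' @param lib an `esynth_library` (descriptors cached).
#' @param id library entry id.
#' @return A `synth_molecule`: graph, level, per-atom open-connection state
#'   (`allowed` partner types for rigid attachment atoms, `conn` remaining
#'   counts for linker atoms), fragment multiset and lazily computed key.
#' @export
synth_from_fragment <- function(lib, id) {
  f <- lib$fragments[[id]]
  if (is.null(f)) stop("unknown fragment id: ", id, call. = FALSE)
  n <- nrow(f$graph$atoms)
  allowed <- rep(list(character(0)), n)
  conn <- integer(n)
  if (f$kind == "rigid") {
    for (a in names(f$conn)) allowed[[as.integer(a)]] <- f$conn[[a]]
  } else {
    conn <- linker_counts(f)
  }
  est <- if (!is.null(lib$descriptors)) {
    unlist(lib$descriptors[id, c("MW", "HBA", "HBD", "logP")])
  }
  structure(list(graph = f$graph, level = 1L,
                 kind = rep(f$kind, n), allowed = allowed, conn = conn,
                 frag_ids = id, key = f$key, est = est),
            class = "synth_molecule")
}

#' @export
print.synth_molecule <- function(x, ...) {
  cat(sprintf("<synth_molecule> level %d (%s): %d heavy atoms%s\n",
              x$level, paste(x$frag_ids, collapse = " + "),
              nrow(x$graph$atoms),
              if (!is.null(x$key)) paste0(", ", x$key) else ""))
  invisible(x)
}

#' @noRd
atom_attachable <- function(m, i) {
  if (m$graph$atoms$hcount[i] < 1L) return(FALSE)
  if (m$kind[i] == "rigid") length(m$allowed[[i]]) > 0L else m$conn[i] >= 1L
}

#' @noRd
compose_pair <- function(m1, a, m2, b) {
  n1 <- nrow(m1$graph$atoms)
  g <- m1$graph
  g$atoms <- rbind(g$atoms, m2$graph$atoms)
  rownames(g$atoms) <- NULL
  b2 <- m2$graph$bonds
  b2$i <- b2$i + n1; b2$j <- b2$j + n1
  g$bonds <- rbind(g$bonds, b2,
                   data.frame(i = a, j = b + n1, order = 1L))
  g$atoms$hcount[a] <- g$atoms$hcount[a] - 1L
  g$atoms$hcount[b + n1] <- g$atoms$hcount[b + n1] - 1L
  g$name <- ""
  out <- structure(list(
    graph = g, level = m1$level + m2$level,
    kind = c(m1$kind, m2$kind),
    allowed = c(m1$allowed, m2$allowed),
    conn = c(m1$conn, m2$conn),
    frag_ids = sort(c(m1$frag_ids, m2$frag_ids)),
    key = NULL,
    est = if (!is.null(m1$est) && !is.null(m2$est)) m1$est + m2$est),
    class = "synth_molecule")
  if (out$kind[a] == "linker") out$conn[a] <- out$conn[a] - 1L
  if (out$kind[b + n1] == "linker") {
    out$conn[b + n1] <- out$conn[b + n1] - 1L
  }
  out
}

#' One attachable atom per symmetry class of the state-annotated graph.
#' Attaching at state-equivalent positions yields isomorphic products with
#' isomorphic open states, so only class representatives are enumerated.
#' @noRd
attachable_reps <- function(m) {
  at <- which(vapply(seq_len(nrow(m$graph$atoms)),
                     function(i) atom_attachable(m, i), logical(1)))
  if (length(at) < 2L) return(at)
  extra <- vapply(seq_len(nrow(m$graph$atoms)), function(i) {
    paste0(m$kind[i], m$conn[i], paste(m$allowed[[i]], collapse = "+"))
  }, character(1))
  cls <- symmetry_classes(m$graph, extra)
  at[!duplicated(cls[at])]
}

#' @noRd
compose_raw <- function(m1, m2, at1 = attachable_reps(m1),
                        at2 = attachable_reps(m2)) {
  out <- list()
  for (a in at1) {
    for (b in at2) {
      k1 <- m1$kind[a]; k2 <- m2$kind[b]
      if (k1 == "linker" && k2 == "linker") next
      if (k1 == "rigid" &&
          !(m2$graph$atoms$sybyl[b] %in% m1$allowed[[a]])) next
      if (k2 == "rigid" &&
          !(m1$graph$atoms$sybyl[a] %in% m2$allowed[[b]])) next
      out[[length(out) + 1L]] <- compose_pair(m1, a, m2, b)
    }
  }
  out
}

#' Compose two partial molecules in all legal orientations
#'
#' Enumerates every single bond between an open attachment atom of one
#' molecule and a compatible open atom of the other: linker-linker bonds are
#' prohibited, a rigid attachment accepts a partner only if the partner's
#' SYBYL type is in its allowed set (rigid-rigid bonds therefore require
#' mutual acceptance), each formed bond consumes one hydrogen and one open
#' connection on each side, and products are deduplicated by canonical key.
#'
#' @param m1,m2 `synth_molecule` objects.
#' @return List of product `synth_molecule`s (possibly empty), each with its
#'   canonical key filled and level `m1$level + m2$level`.
#' @export
compose <- function(m1, m2) {
  cands <- compose_raw(m1, m2)
  if (length(cands) == 0L) return(list())
  keys <- canonical_keys(lapply(cands, function(m) m$graph))
  keep <- !duplicated(keys)
  cands <- cands[keep]
  for (k in seq_along(cands)) cands[[k]]$key <- keys[keep][k]
  cands
}

#' @noRd
canonical_ranks_batch <- function(mols) {
  rk <- ChemmineOB::forEachMol("SDF", sdf_text(mols), function(m) {
    ChemmineOB::canonicalNumbering_OB(m)
  })
  lapply(seq_along(mols), function(k) {
    r <- as.integer(unlist(rk[[k]]))
    if (length(r) != nrow(mols[[k]]$atoms) || anyDuplicated(r)) {
      r <- seq_len(nrow(mols[[k]]$atoms))
    }
    r
  })
}

#' Canonical open-connection state signature
#'
#' Plain canonical keys identify the molecular graph only; two isomorphic
#' intermediates can still differ in their remaining connectivity (and hence
#' in what they can grow into). The state key appends the per-atom open
#' state in canonical atom order, so deduplicating intermediates on it never
#' discards a state that could lead to new products.
#' @noRd
state_signature <- function(m, key, ranks) {
  st <- vapply(seq_len(nrow(m$graph$atoms)), function(i) {
    paste0(substr(m$kind[i], 1, 1), m$conn[i], "<",
           paste(m$allowed[[i]], collapse = "+"), ">", m$graph$atoms$hcount[i])
  }, character(1))
  paste0(key, "||", paste(st[order(ranks)], collapse = ";"))
}

#' @noRd
prefilter_pass <- function(m, lib, cfg) {
  if (!isTRUE(cfg$prefilter)) return(TRUE)
  e <- m$est
  if (is.null(e)) {
    est <- estimate_descriptors(m, lib, cfg$calibration)
    return(passes_ro5(est, cfg$thresholds, "pre_synthesis"))
  }
  if (!is.null(cfg$calibration)) {
    md <- cfg$calibration$model
    e[["MW"]] <- md$MW$slope * e[["MW"]] + md$MW$intercept
    e[["HBD"]] <- max(0, md$HBD$slope * e[["HBD"]] + md$HBD$intercept)
    e[["HBA"]] <- max(0, md$HBA$slope * e[["HBA"]] + md$HBA$intercept)
  }
  e[["MW"]] <= cfg$thresholds$max_MW &&
    e[["HBD"]] <= cfg$thresholds$max_HBD &&
    e[["HBA"]] <= cfg$thresholds$max_HBA
}

#' Exhaustive level-based synthesis
#'
#' Level 1 holds the library fragments; each level k is the set of all legal
#' single-fragment extensions of level k-1 molecules, completed before the
#' next level starts. Intermediate states are deduplicated by canonical key
#' plus open-connection signature (complete: on small instances the output
#' equals a brute-force enumeration); the returned set is deduplicated by
#' plain canonical key across all levels, each key reported at the lowest
#' level where it appeared.
#'
#' @param lib an `esynth_library`.
#' @param cfg a [synthesis_config()].
#' @return An `esynth_synthesis`: `molecules` (list of `synth_molecule` keyed
#'   by canonical SMILES), `level_counts`, `truncated` flag and the config.
#' @export
synthesize_exhaustive <- function(lib, cfg = synthesis_config()) {
  lib <- set_linker_mode(lib, cfg$linker_mode)
  lib <- ensure_descriptors(lib)
  if (length(lib$fragments) == 0L) stop("empty fragment library", call. = FALSE)
  ids <- sort(names(lib$fragments))
  ones <- lapply(ids, function(id) synth_from_fragment(lib, id))
  out <- new.env(parent = emptyenv())
  seen_states <- new.env(parent = emptyenv())
  for (m in ones) {
    if (is.null(out[[m$key]])) out[[m$key]] <- m
  }
  level <- ones
  level_counts <- c(`1` = length(ones))
  one_reps <- lapply(ones, attachable_reps)
  for (k in seq(2L, cfg$max_level)) {
    cands <- list()
    for (m in level) {
      m_reps <- attachable_reps(m)
      for (fi in seq_along(ones)) {
        cands <- c(cands, compose_raw(m, ones[[fi]], m_reps, one_reps[[fi]]))
      }
    }
    if (length(cands) == 0L) break
    keys <- canonical_keys(lapply(cands, function(m) m$graph))
    ranks <- canonical_ranks_batch(lapply(cands, function(m) m$graph))
    nxt <- list()
    for (ci in seq_along(cands)) {
      m <- cands[[ci]]
      m$key <- keys[ci]
      sig <- state_signature(m, keys[ci], ranks[[ci]])
      if (!is.null(seen_states[[sig]])) next
      seen_states[[sig]] <- TRUE
      if (!prefilter_pass(m, lib, cfg)) next
      nxt[[length(nxt) + 1L]] <- m
      if (is.null(out[[m$key]])) out[[m$key]] <- m
    }
    level_counts[as.character(k)] <- length(nxt)
    if (length(nxt) == 0L) break
    level <- nxt
  }
  finalize_synthesis(out, lib, cfg, level_counts, truncated = FALSE)
}

#' @noRd
finalize_synthesis <- function(out, lib, cfg, level_counts, truncated) {
  if (is.environment(out)) {
    keys <- sort(ls(out))
    out <- mget(keys, envir = out)
  }
  if (isTRUE(cfg$final_filter) && length(out)) {
    ex <- lipinski_descriptors(lapply(out, function(m) m$graph))
    keep <- vapply(seq_len(nrow(ex)), function(i) {
      passes_ro5(ex[i, , drop = FALSE], cfg$thresholds, "final")
    }, logical(1))
    out <- out[keep]
  }
  structure(list(molecules = out, level_counts = level_counts,
                 truncated = truncated, config = cfg),
            class = "esynth_synthesis")
}

#' @export
print.esynth_synthesis <- function(x, ...) {
  cat(sprintf("<synthesis> %d unique molecule(s)%s; per level: %s\n",
              length(x$molecules),
              if (x$truncated) " [truncated]" else "",
              paste(sprintf("%s:%d", names(x$level_counts), x$level_counts),
                    collapse = " ")))
  invisible(x)
}

#' Canonical keys of a synthesis result
#' @param res an `esynth_synthesis`.
#' @return sorted character vector of canonical SMILES.
#' @export
synthesis_keys <- function(res) sort(names(res$molecules))

#' Lowest level at which each key was synthesized
#' @param res an `esynth_synthesis`.
#' @return named integer vector (key -> level).
#' @export
synthesis_levels <- function(res) {
  vapply(res$molecules, function(m) m$level, integer(1))
}

#' Bounded worklist synthesis
#'
#' The bounded alternative: one FIFO worklist per level with an explicit
#' capacity; when level l+1's worklist fills, the remaining level-l items are
#' forgone and processing moves on, which (with the wall-time budget)
#' guarantees termination. Every candidate passes the pre-synthesis
#' drug-likeness gate and the Bloom filter acceptance (level filter, then
#' global filter), so molecules with the same canonical SMILES are filtered
#' as redundant across levels. Output is always a subset of
#' [synthesize_exhaustive()] under the same configuration.
#'
#' @param lib an `esynth_library`.
#' @param cfg a [synthesis_config()].
#' @return An `esynth_synthesis`; `truncated` is TRUE when the wall-time
#'   budget expired before the worklists were exhausted.
#' @export
synthesize_bounded <- function(lib, cfg = synthesis_config()) {
  t0 <- Sys.time()
  lib <- set_linker_mode(lib, cfg$linker_mode)
  lib <- ensure_descriptors(lib)
  if (length(lib$fragments) == 0L) stop("empty fragment library", call. = FALSE)
  ids <- sort(names(lib$fragments))
  ones <- lapply(ids, function(id) synth_from_fragment(lib, id))
  filters <- bloom_filter_set(cfg$max_level, cfg$bloom_n, cfg$bloom_p)
  one_reps <- lapply(ones, attachable_reps)
  out <- new.env(parent = emptyenv())
  work <- vector("list", cfg$max_level)
  truncated <- FALSE
  over_time <- function() {
    as.numeric(difftime(Sys.time(), t0, units = "secs")) > cfg$wall_time_limit
  }
  for (m in ones) {
    if (accept_molecule(filters, 1L, m$key)) {
      out[[m$key]] <- m
      if (length(work[[1L]]) < cfg$level_capacity) {
        work[[1L]] <- c(work[[1L]], list(m))
      }
    }
  }
  level_counts <- c(`1` = length(work[[1L]]))
  if (over_time()) truncated <- TRUE
  if (!truncated) {
    for (l in seq_len(cfg$max_level - 1L)) {
      queue <- work[[l]]
      if (length(queue) == 0L) next
      # compose the whole level, tagging candidates with their source item,
      # so canonical keys can be computed in one batched conversion
      cands <- list()
      src <- integer(0)
      for (qi in seq_along(queue)) {
        q_reps <- attachable_reps(queue[[qi]])
        for (fi in seq_along(ones)) {
          cc <- compose_raw(queue[[qi]], ones[[fi]], q_reps, one_reps[[fi]])
          if (length(cc)) {
            cands <- c(cands, cc)
            src <- c(src, rep(qi, length(cc)))
          }
        }
        if (over_time()) { truncated <- TRUE; break }
      }
      n_ro5 <- 0L; n_dup <- 0L
      if (!truncated && length(cands)) {
        keys <- canonical_keys(lapply(cands, function(x) x$graph))
        nxt <- list()
        cutoff <- Inf  # items after this index are forgone once l+1 fills
        for (ci in seq_along(cands)) {
          if (src[ci] > cutoff) next
          cand <- cands[[ci]]
          cand$key <- keys[ci]
          if (!prefilter_pass(cand, lib, cfg)) { n_ro5 <- n_ro5 + 1L; next }
          if (!accept_molecule(filters, l + 1L, cand$key)) {
            n_dup <- n_dup + 1L
            next
          }
          out[[cand$key]] <- cand
          if (length(nxt) < cfg$level_capacity) {
            nxt[[length(nxt) + 1L]] <- cand
          } else {
            cutoff <- src[ci]  # forgo remaining items at level l
          }
        }
        work[[l + 1L]] <- nxt
      }
      if (isTRUE(cfg$verbose)) {
        esynth_log("INFO", "synth", sprintf(
          "level %d: generated %d, ro5-rejected %d, bloom-rejected %d, accepted %d",
          l + 1L, length(cands), n_ro5, n_dup, length(work[[l + 1L]])))
      }
      level_counts[as.character(l + 1L)] <- length(work[[l + 1L]])
      if (over_time()) truncated <- TRUE
      if (truncated) break
    }
  }
  finalize_synthesis(out, lib, cfg, level_counts, truncated)
}

#' Pre-synthesis drug-likeness gate
#'
#' TRUE when the (calibrated) estimated MW, HBD and HBA respect the
#' thresholds; logP is deliberately not checked before synthesis.
#'
#' @param mol a `synth_molecule`.
#' @param lib the library providing cached fragment descriptors.
#' @param thresholds a [ro5_thresholds()] list.
#' @param calibration optional `esynth_calibration`.
#' @return logical.
#' @export
prefilter <- function(mol, lib, thresholds = ro5_thresholds("modified"),
                      calibration = NULL) {
  est <- estimate_descriptors(mol, ensure_descriptors(lib), calibration)
  passes_ro5(est, thresholds, "pre_synthesis")
}
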