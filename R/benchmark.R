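# Benchmarking protocols: self-benchmarking (rebuild each compound from its
# own fragments, score the best fingerprint match against the parent) and
# leave-one-cluster-out cross-validation (rebuild compounds of a held-out
# cluster from fragments of the remaining clusters, prefilter products by
# 1D-TC and rescore survivors by MCS-based 2D-TC).

#' Is a target reconstructible from a fragment library?
#'
#' Necessary condition only: every rigid fragment key of the target's
#' decomposition must be present in the library. Linker availability and
#' connectivity patterns can still block reconstruction, so the estimate is
#' conservative (an upper bound on what synthesis can rebuild).
#'
#' @param target a typed `molecule_graph`.
#' @param lib an `esynth_library`.
#' @return logical.
#' @export
reconstructible <- function(target, lib) {
  dec <- decompose(target, annotate = FALSE)
  kinds <- vapply(dec$fragments, function(f) f$kind, character(1))
  rk <- canonical_keys(lapply(dec$fragments[kinds == "rigid"],
                              function(f) f$graph))
  all(rk %in% rigid_keys(lib))
}

#' Default synthesis configuration for benchmarking
#'
#' Unsaturated linkers (connectivity restricted to the patterns observed in
#' the parents), level capacity 50000, up to 6 fragments per molecule.
#'
#' @param ... overrides passed to [synthesis_config()].
#' @return A `synthesis_config`.
#' @export
benchmark_config <- function(...) {
  args <- list(...)
  defaults <- list(max_level = 6L, level_capacity = 50000,
                   linker_mode = "unsaturated", bloom_n = 1e5,
                   wall_time_limit = 3600)
  defaults[names(args)] <- args
  do.call(synthesis_config, defaults)
}

#' Self-benchmarking test
#'
#' Each active compound is decomposed into fragments, the bounded synthesis
#' is run on its own fragment library, and the best fingerprint Tanimoto
#' between any synthesized product and the parent is reported. Compounds
#' consisting of a single fragment cannot be decomposed, so no synthesis is
#' executed and they count as failures in the cumulative fractions.
#'
#' @param actives list of typed `molecule_graph`s.
#' @param cfg a [synthesis_config()]; defaults to [benchmark_config()].
#' @param cutoffs TC cutoffs for the cumulative fractions.
#' @return An `esynth_benchmark` report: `per_compound` data.frame,
#'   `fractions` (named by cutoff), and the config.
#' @export
self_benchmark <- function(actives, cfg = benchmark_config(),
                           cutoffs = c(1.0, 0.8, 0.6, 0.5)) {
  if (length(actives) == 0L) stop("no active compounds", call. = FALSE)
  rows <- lapply(seq_along(actives), function(i) {
    parent <- actives[[i]]
    t0 <- Sys.time()
    dec <- decompose(parent)
    n_frag <- length(dec$fragments)
    if (n_frag < 2L) {
      return(data.frame(name = parent$name, n_fragments = n_frag,
                        executed = FALSE, n_products = 0L,
                        max_tc = NA_real_, level = NA_integer_,
                        seconds = as.numeric(difftime(Sys.time(), t0,
                                                      units = "secs"))))
    }
    lib <- consolidate(dec, linker_mode = cfg$linker_mode)
    res <- synthesize_bounded(lib, cfg)
    prods <- res$molecules[vapply(res$molecules, function(m) m$level,
                                  integer(1)) >= 2L]
    if (length(prods) == 0L) {
      return(data.frame(name = parent$name, n_fragments = n_frag,
                        executed = TRUE, n_products = 0L,
                        max_tc = 0, level = NA_integer_,
                        seconds = as.numeric(difftime(Sys.time(), t0,
                                                      units = "secs"))))
    }
    tc <- tanimoto_to(parent, lapply(prods, function(m) m$graph))
    best <- which.max(tc)
    data.frame(name = parent$name, n_fragments = n_frag, executed = TRUE,
               n_products = length(prods), max_tc = max(tc),
               level = prods[[best]]$level,
               seconds = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  })
  per <- do.call(rbind, rows)
  fractions <- vapply(cutoffs, function(ct) {
    mean(per$executed & !is.na(per$max_tc) & per$max_tc >= ct)
  }, numeric(1))
  names(fractions) <- sprintf("tc>=%g", cutoffs)
  structure(list(type = "self", per_compound = per, fractions = fractions,
                 cutoffs = cutoffs, config = cfg),
            class = "esynth_benchmark")
}

#' Leave-one-cluster-out cross-validation test
#'
#' Actives are clustered at a 1D-TC threshold; each cluster in turn is held
#' out and a fragment library is consolidated from the decompositions of all
#' other clusters. Synthesized products are prefiltered at 1D-TC >= 0.5
#' against the held-out compound (maximum over products) and survivors are
#' rescored with the MCS-based 2D-TC; the report gives the fraction of
#' held-out compounds rebuilt at 2D-TC >= 0.6 and >= 0.5 plus the fraction
#' that was reconstructible at all (rigid inventory present).
#'
#' @param actives list of typed `molecule_graph`s.
#' @param cfg a [synthesis_config()]; defaults to [benchmark_config()].
#' @param tc_cluster clustering threshold (1D-TC).
#' @param tc_prefilter product prefilter threshold (1D-TC).
#' @param mcs_time_budget seconds per MCS comparison.
#' @return An `esynth_benchmark` report.
#' @export
cross_validate <- function(actives, cfg = benchmark_config(),
                           tc_cluster = 0.7, tc_prefilter = 0.5,
                           mcs_time_budget = 5) {
  cl <- cluster_compounds(actives, tc_cluster)
  if (length(cl$clusters) < 2L) {
    stop("cross-validation needs at least two clusters", call. = FALSE)
  }
  decs <- lapply(actives, decompose)
  rows <- list()
  for (ci in seq_along(cl$clusters)) {
    held <- cl$clusters[[ci]]
    train <- setdiff(seq_along(actives), held)
    frags <- unlist(lapply(decs[train], function(d) d$fragments),
                    recursive = FALSE)
    lib <- consolidate(frags, linker_mode = cfg$linker_mode)
    res <- synthesize_bounded(lib, cfg)
    prods <- res$molecules[vapply(res$molecules, function(m) m$level,
                                  integer(1)) >= 2L]
    pgraphs <- lapply(prods, function(m) m$graph)
    for (i in held) {
      target <- actives[[i]]
      rec <- reconstructible(target, lib)
      best1d <- 0; best2d <- NA_real_
      if (length(pgraphs)) {
        tc <- tanimoto_to(target, pgraphs)
        best1d <- max(tc)
        surv <- which(tc >= tc_prefilter)
        if (length(surv)) {
          tc2 <- vapply(surv, function(s) {
            mcs_tc(target, pgraphs[[s]], mcs_time_budget)
          }, numeric(1))
          if (any(!is.na(tc2))) best2d <- max(tc2, na.rm = TRUE)
        }
      }
      rows[[length(rows) + 1L]] <- data.frame(
        name = target$name, cluster = ci, reconstructible = rec,
        best_tc1d = best1d, best_tc2d = best2d)
    }
  }
  per <- do.call(rbind, rows)
  hit <- function(ct) mean(!is.na(per$best_tc2d) & per$best_tc2d >= ct)
  fractions <- c(`tc2d>=0.6` = hit(0.6), `tc2d>=0.5` = hit(0.5),
                 reconstructible = mean(per$reconstructible))
  structure(list(type = "cross", per_compound = per, fractions = fractions,
                 clusters = cl, config = cfg),
            class = "esynth_benchmark")
}

#' @export
print.esynth_benchmark <- function(x, ...) {
  cat(sprintf("<%s-benchmark> %d compound(s)\n", x$type,
              nrow(x$per_compound)))
  for (nm in names(x$fractions)) {
    cat(sprintf("  %-16s %.3f\n", nm, x$fractions[[nm]]))
  }
  invisible(x)
}

#' Cumulative reconstruction curve of a self-benchmark report
#'
#' Fraction of compounds whose best product matches the parent at or above
#' each TC cutoff; monotone non-increasing in the cutoff.
#'
#' @param x an `esynth_benchmark` from [self_benchmark()].
#' @param ... passed to [graphics::plot()].
#' @export
plot.esynth_benchmark <- function(x, ...) {
  ct <- sort(x$cutoffs)
  fr <- vapply(ct, function(c0) {
    mean(x$per_compound$executed & !is.na(x$per_compound$max_tc) &
           x$per_compound$max_tc >= c0)
  }, numeric(1))
  graphics::plot(ct, fr, type = "b", xlab = "Tanimoto coefficient cutoff",
                 ylab = "cumulative fraction reconstructed", ylim = c(0, 1),
                 ...)
  invisible(x)
}
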