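# Lipinski descriptors: exact values for whole molecules, additive estimates
# from fragment values, linear calibration of the estimates, Rule-of-Five
# filtering (classic and modified cutoffs) and ROC evaluation of the
# estimators. HBA is the N+O count and HBD the number of N-H/O-H groups
# (classic Lipinski counting); logP uses Open Babel's atomic-contribution
# model so that fragment estimates and exact values are commensurable.

#' Exact Lipinski descriptors of molecular graphs
#'
#' @param mols a `molecule_graph` or list of them.
#' @return data.frame with columns `MW`, `HBA`, `HBD`, `logP`.
#' @export
lipinski_descriptors <- function(mols) {
  if (inherits(mols, "molecule_graph")) mols <- list(mols)
  logp <- as.numeric(ob_descriptors(mols)$logP)
  out <- data.frame(
    MW = vapply(mols, molecular_weight, numeric(1)),
    HBA = vapply(mols, function(m) sum(m$atoms$element %in% c("N", "O")),
                 numeric(1)),
    HBD = vapply(mols, function(m) {
      sum(m$atoms$element %in% c("N", "O") & m$atoms$hcount >= 1L)
    }, numeric(1)),
    logP = logp)
  rownames(out) <- NULL
  out
}

#' Lipinski descriptors of a saturated fragment
#'
#' Exact descriptors computed on the hydrogen-saturated fragment graph; these
#' are the additive contributions cached with a fragment library.
#'
#' @param frag an `esynth_fragment`.
#' @return one-row data.frame `MW`, `HBA`, `HBD`, `logP`.
#' @export
fragment_descriptors <- function(frag) {
  if (anyNA(frag$graph$atoms$sybyl)) {
    stop("fragment has untyped atoms", call. = FALSE)
  }
  lipinski_descriptors(frag$graph)
}

#' Cache per-fragment descriptors on a library
#'
#' @param lib an `esynth_library`.
#' @return The library with a `descriptors` data.frame (rownames = entry ids).
#' @export
ensure_descriptors <- function(lib) {
  if (!is.null(lib$descriptors)) return(lib)
  d <- lipinski_descriptors(lapply(lib$fragments, function(f) f$graph))
  rownames(d) <- names(lib$fragments)
  lib$descriptors <- d
  lib
}

#' Fragment-additive descriptor estimate for a synthesized molecule
#'
#' The raw estimate is the sum of the cached descriptors of the constituent
#' fragments; when a calibration model is supplied, each descriptor is mapped
#' through its fitted linear transform (counts clamped at zero). HBD
#' over-predicts before calibration because fragments are saturated with
#' hydrogens, some of which can donate hydrogen bonds.
#'
#' @param mol a `synth_molecule` (or a character vector of library entry ids).
#' @param lib the `esynth_library` the molecule was built from (descriptors
#'   cached via [ensure_descriptors()]).
#' @param calibration optional `esynth_calibration`.
#' @return one-row data.frame `MW`, `HBA`, `HBD`, `logP` with attribute
#'   `calibrated`.
#' @export
estimate_descriptors <- function(mol, lib, calibration = NULL) {
  ids <- if (is.character(mol)) mol else mol$frag_ids
  d <- lib$descriptors
  if (is.null(d)) stop("library descriptors not cached; call ensure_descriptors",
                       call. = FALSE)
  if (!all(ids %in% rownames(d))) {
    stop("missing descriptor cache entry for ",
         paste(setdiff(ids, rownames(d)), collapse = ", "), call. = FALSE)
  }
  est <- as.data.frame(t(colSums(d[ids, , drop = FALSE])))
  if (!is.null(calibration)) est <- apply_calibration(est, calibration)
  attr(est, "calibrated") <- !is.null(calibration)
  est
}

#' Fit a linear calibration of estimated against exact descriptors
#'
#' Least-squares line per descriptor mapping the fragment-additive estimate
#' onto the exact value, with the Pearson correlation of the fitting set as
#' diagnostic.
#'
#' @param exact data.frame of exact descriptors (`MW`, `HBA`, `HBD`, `logP`).
#' @param raw data.frame of raw estimates, same shape.
#' @return An `esynth_calibration`: per descriptor `slope`, `intercept`,
#'   `pcc`, plus the fitting-set size.
#' @export
calibrate <- function(exact, raw) {
  stopifnot(nrow(exact) == nrow(raw), nrow(exact) >= 2)
  descs <- c("MW", "HBA", "HBD", "logP")
  model <- lapply(descs, function(d) {
    x <- raw[[d]]; y <- exact[[d]]
    if (stats::sd(x) == 0) {
      stop("degenerate (constant) estimates for ", d, call. = FALSE)
    }
    fit <- stats::lm(y ~ x)
    list(slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         pcc = suppressWarnings(stats::cor(x, y)))
  })
  names(model) <- descs
  structure(list(model = model, n = nrow(exact)),
            class = "esynth_calibration")
}

#' @export
print.esynth_calibration <- function(x, ...) {
  cat(sprintf("<calibration> fitted on %d pairs\n", x$n))
  for (d in names(x$model)) {
    m <- x$model[[d]]
    cat(sprintf("  %-4s slope=%.4f intercept=%+.4f pcc=%.4f\n",
                d, m$slope, m$intercept, m$pcc))
  }
  invisible(x)
}

#' Apply a calibration model to raw descriptor estimates
#'
#' @param est one-or-more-row data.frame of raw estimates.
#' @param calibration an `esynth_calibration`.
#' @return data.frame of calibrated estimates (HBA/HBD clamped at 0).
#' @export
apply_calibration <- function(est, calibration) {
  for (d in names(calibration$model)) {
    m <- calibration$model[[d]]
    est[[d]] <- m$slope * est[[d]] + m$intercept
  }
  est$HBA <- pmax(est$HBA, 0)
  est$HBD <- pmax(est$HBD, 0)
  est
}

#' Save / load calibration models as JSON
#'
#' @param calibration an `esynth_calibration`.
#' @param path JSON file path.
#' @return `path` (write) or the model (read).
#' @export
write_calibration <- function(calibration, path) {
  jsonlite::write_json(unclass(calibration), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  structure(jsonlite::read_json(path, simplifyVector = TRUE),
            class = "esynth_calibration")
}

#' Packaged default calibration model
#'
#' Fitted on the packaged synthetic fixture panel (see
#' `scripts/fit-default-calibration.R` in the source repository).
#'
#' @return An `esynth_calibration`.
#' @export
default_calibration <- function() {
  read_calibration(system.file("extdata", "calibration-default.json",
                               package = "esynth", mustWork = TRUE))
}

#' Rule-of-Five thresholds
#'
#' Classic Lipinski cutoffs (MW 500, HBD 5, HBA 10, logP 5) or the modified
#' cutoffs (MW 570, HBD 5, HBA 10, logP 7.2) chosen so that the large
#' majority of known actives comply.
#'
#' @param which `"modified"` (default) or `"classic"`.
#' @return list with `max_MW`, `max_HBD`, `max_HBA`, `max_logP`.
#' @export
ro5_thresholds <- function(which = c("modified", "classic")) {
  which <- match.arg(which)
  if (which == "modified") {
    list(max_MW = 570, max_HBD = 5, max_HBA = 10, max_logP = 7.2)
  } else {
    list(max_MW = 500, max_HBD = 5, max_HBA = 10, max_logP = 5)
  }
}

#' Rule-of-Five compliance test
#'
#' At the pre-synthesis stage only MW, HBD and HBA are checked (estimated
#' logP is too weak a classifier to gate intermediates, and attaching a
#' hydrophilic moiety can bring a high-logP intermediate back into range);
#' the final stage additionally checks logP. All comparisons are inclusive.
#'
#' @param est one-row data.frame `MW`, `HBA`, `HBD`, `logP`.
#' @param thresholds a [ro5_thresholds()] list.
#' @param stage `"pre_synthesis"` or `"final"`.
#' @return logical.
#' @export
passes_ro5 <- function(est, thresholds = ro5_thresholds("modified"),
                       stage = c("pre_synthesis", "final")) {
  stage <- match.arg(stage)
  ok <- est$MW <= thresholds$max_MW &&
    est$HBD <= thresholds$max_HBD &&
    est$HBA <= thresholds$max_HBA
  if (stage == "final") ok <- ok && est$logP <= thresholds$max_logP
  isTRUE(ok)
}

#' Area under the ROC curve by the rank statistic
#'
#' Probability that a random positive outranks a random negative, with ties
#' counted 0.5 (the Mann-Whitney formulation).
#'
#' @param scores numeric classifier scores (higher = more positive).
#' @param labels logical (or 0/1) true labels.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L) {
    stop("AUC undefined: both classes must be present", call. = FALSE)
  }
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
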