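# Reading and writing molecule sets (SDF V2000 and SMILES files). Input is
# normalized through Open Babel so that bond orders arrive in Kekule form and
# SMILES records gain a connection table; records with unsupported chemistry
# are skipped with a warning rather than aborting the whole file.

#' Read molecules from an SDF or SMILES file
#'
#' Each record becomes a typed [molecule_graph()] with hydrogens counted and
#' SYBYL atom types assigned. Records containing elements or atom environments
#' outside the supported SYBYL set, or failing the valence model, are skipped
#' with a logged warning.
#'
#' @param path input file.
#' @param format `"sdf"` or `"smiles"` (guessed from the extension when
#'   missing).
#' @return List of `molecule_graph` objects.
#' @export
read_molecules <- function(path, format = c("sdf", "smiles")) {
  if (!file.exists(path)) stop("cannot read file: ", path, call. = FALSE)
  format <- if (missing(format)) guess_format(path) else match.arg(format)
  text <- paste0(paste(readLines(path, warn = FALSE), collapse = "\n"), "\n")
  from <- switch(format, sdf = "SDF", smiles = "SMI")
  norm <- tryCatch(ob_convert(from, "SDF", text), error = function(e) {
    stop("unreadable ", format, " input: ", conditionMessage(e), call. = FALSE)
  })
  raw <- parse_sdf_text(norm)
  out <- list()
  for (k in seq_along(raw)) {
    mol <- tryCatch({
      m <- fill_hydrogen_counts(raw[[k]])
      m <- assign_sybyl_types(m, strict = TRUE)
      validate_molecule_graph(m)
      attr(m, "sdf_fields") <- attr(raw[[k]], "sdf_fields")
      m
    }, error = function(e) {
      esynth_log("WARN", "io", sprintf("skipping record %d (%s): %s", k,
                                       raw[[k]]$name, conditionMessage(e)))
      NULL
    })
    if (!is.null(mol)) out[[length(out) + 1L]] <- mol
  }
  if (length(out) == 0L) {
    stop("no valid molecule records in ", path, call. = FALSE)
  }
  out
}

#' Write molecules to an SDF or SMILES file
#'
#' Fragment annotations (kind, connection table) found on the objects are
#' preserved as `ESYNTH_*` SDF data fields so that a written fragment library
#' can be read back losslessly.
#'
#' @param mols list of `molecule_graph` or `esynth_fragment` objects.
#' @param path output file.
#' @param format `"sdf"` or `"smiles"`.
#' @return Number of records written, invisibly.
#' @export
write_molecules <- function(mols, path, format = c("sdf", "smiles")) {
  format <- if (missing(format)) guess_format(path) else match.arg(format)
  if (inherits(mols, "molecule_graph") || inherits(mols, "esynth_fragment")) {
    mols <- list(mols)
  }
  graphs <- lapply(mols, function(m) {
    if (inherits(m, "esynth_fragment")) m$graph else m
  })
  fields <- lapply(mols, fragment_sdf_fields)
  ok <- tryCatch({
    if (format == "sdf") {
      writeLines(sub("\n$", "", sdf_text(graphs, fields = fields)), path)
    } else {
      keys <- if (length(graphs)) canonical_keys(graphs) else character()
      nms <- vapply(graphs, function(m) m$name, character(1))
      writeLines(trimws(paste(keys, nms)), path)
    }
    TRUE
  }, error = function(e) {
    stop("cannot write ", path, ": ", conditionMessage(e), call. = FALSE)
  })
  invisible(length(graphs))
}

#' Build a typed molecular graph from a SMILES string
#'
#' @param smiles SMILES string.
#' @param name molecule title.
#' @return A typed, hydrogen-counted `molecule_graph`.
#' @export
smiles_to_molecule <- function(smiles, name = "") {
  sdf <- ob_convert("SMI", "SDF", paste0(smiles, "\n"))
  mols <- parse_sdf_text(sdf)
  if (length(mols) != 1L) stop("unparsable SMILES: ", smiles, call. = FALSE)
  m <- fill_hydrogen_counts(mols[[1]])
  m$name <- name
  assign_sybyl_types(m)
}

#' @noRd
guess_format <- function(path) {
  if (grepl("\\.(smi|smiles|can)$", path, ignore.case = TRUE)) "smiles"
  else "sdf"
}

#' @noRd
esynth_log <- function(level, module, message) {
  cat(sprintf("%s  %s  %s\n", level, module, message), file = stderr())
}
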