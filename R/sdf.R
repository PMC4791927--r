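# SDF (V2000) text generation and parsing for molecule_graph objects.
#
# The writer emits Kekule bond orders, formal charges as M  CHG lines and
# optional data fields (used for ESYNTH_KIND / ESYNTH_CONNECTIONS annotations).
# The parser folds explicit hydrogen atoms into the heavy-atom hydrogen
# counts, so graphs always stay heavy-atom-only.

#' Render molecular graphs as SDF (V2000) text
#'
#' @param mols a `molecule_graph` or list of them.
#' @param fields optional list (parallel to `mols`) of named character vectors
#'   written as SDF data fields.
#' @return A single character string of concatenated SDF records.
#' @export
sdf_text <- function(mols, fields = NULL) {
  if (inherits(mols, "molecule_graph")) mols <- list(mols)
  recs <- vapply(seq_along(mols), function(k) {
    sdf_record(mols[[k]], if (is.null(fields)) NULL else fields[[k]])
  }, character(1))
  paste0(paste(recs, collapse = ""), "")
}

#' @noRd
sdf_record <- function(mol, fields = NULL) {
  a <- mol$atoms
  b <- mol$bonds
  lines <- c(mol$name, " esynth          2D", "")
  lines <- c(lines, sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                            nrow(a), nrow(b)))
  lines <- c(lines, sprintf(
    "%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
    a$x, a$y, a$z, a$element))
  if (nrow(b)) {
    lines <- c(lines, sprintf("%3d%3d%3d  0  0  0  0", b$i, b$j, b$order))
  }
  chg <- which(a$charge != 0L)
  while (length(chg)) {
    take <- chg[seq_len(min(8L, length(chg)))]
    chg <- chg[-seq_len(min(8L, length(chg)))]
    lines <- c(lines, paste0(sprintf("M  CHG%3d", length(take)),
                             paste(sprintf("%4d%4d", take,
                                           a$charge[take]), collapse = "")))
  }
  lines <- c(lines, "M  END")
  for (nm in names(fields)) {
    lines <- c(lines, sprintf(">  <%s>", nm), fields[[nm]], "")
  }
  lines <- c(lines, "$$$$")
  paste0(paste(lines, collapse = "\n"), "\n")
}

#' Parse SDF (V2000) text into molecular graphs
#'
#' Explicit hydrogen atoms are folded into their heavy neighbour's hydrogen
#' count; remaining hydrogen counts are completed from the valence model.
#' Data fields are attached as the `sdf_fields` attribute of each graph.
#'
#' @param text SDF text (one or more records).
#' @return List of `molecule_graph` objects (unvalidated atoms may carry
#'   unsupported elements; callers filter via typing).
#' @export
parse_sdf_text <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  ends <- which(trimws(lines) == "$$$$")
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  mols <- vector("list", length(ends))
  for (r in seq_along(ends)) {
    rec <- lines[starts[r]:(ends[r] - 1L)]
    mols[[r]] <- parse_sdf_record(rec)
  }
  mols[!vapply(mols, is.null, logical(1))]
}

#' @noRd
parse_sdf_record <- function(rec) {
  if (length(rec) < 4L) return(NULL)
  name <- trimws(rec[1])
  counts <- rec[4]
  na <- as.integer(substr(counts, 1, 3))
  nb <- as.integer(substr(counts, 4, 6))
  if (is.na(na) || na < 1L) return(NULL)
  arows <- rec[5:(4 + na)]
  atoms <- data.frame(
    element = trimws(substr(arows, 32, 34)),
    charge = 0L,
    x = as.numeric(substr(arows, 1, 10)),
    y = as.numeric(substr(arows, 11, 20)),
    z = as.numeric(substr(arows, 21, 30)),
    stringsAsFactors = FALSE)
  # legacy atom-block charge codes (superseded by M  CHG when present)
  ccode <- suppressWarnings(as.integer(substr(arows, 37, 39)))
  ccode[is.na(ccode)] <- 0L
  legacy <- c(`1` = 3L, `2` = 2L, `3` = 1L, `5` = -1L, `6` = -2L, `7` = -3L)
  bonds <- data.frame(i = integer(), j = integer(), order = integer())
  if (nb > 0L) {
    brows <- rec[(5 + na):(4 + na + nb)]
    bonds <- data.frame(
      i = as.integer(substr(brows, 1, 3)),
      j = as.integer(substr(brows, 4, 6)),
      order = as.integer(substr(brows, 7, 9)))
  }
  body <- if (length(rec) > 4 + na + nb) rec[(5 + na + nb):length(rec)] else
    character()
  chg_lines <- grep("^M  CHG", body, value = TRUE)
  if (length(chg_lines)) {
    for (cl in chg_lines) {
      nn <- as.integer(substr(cl, 7, 9))
      for (k in seq_len(nn)) {
        off <- 10L + (k - 1L) * 8L
        idx <- as.integer(substr(cl, off, off + 3L))
        val <- as.integer(substr(cl, off + 4L, off + 7L))
        atoms$charge[idx] <- val
      }
    }
  } else {
    hit <- ccode %in% as.integer(names(legacy))
    atoms$charge[hit] <- legacy[as.character(ccode[hit])]
  }
  fields <- parse_sdf_fields(body)
  mol <- fold_explicit_hydrogens(atoms, bonds, name)
  if (is.null(mol)) return(NULL)
  attr(mol, "sdf_fields") <- fields
  mol
}

#' @noRd
parse_sdf_fields <- function(body) {
  tags <- grep("^>", body)
  out <- list()
  for (t in tags) {
    nm <- sub("^>.*<([^>]+)>.*$", "\\1", body[t])
    vals <- character()
    k <- t + 1L
    while (k <= length(body) && nzchar(trimws(body[k])) &&
           !startsWith(body[k], ">")) {
      vals <- c(vals, body[k])
      k <- k + 1L
    }
    out[[nm]] <- vals
  }
  out
}

#' @noRd
fold_explicit_hydrogens <- function(atoms, bonds, name) {
  isH <- atoms$element == "H"
  if (any(isH)) {
    keep <- which(!isH)
    if (length(keep) == 0L) return(NULL)
    map <- integer(nrow(atoms)); map[keep] <- seq_along(keep)
    sel <- !isH[bonds$i] & !isH[bonds$j]
    bonds <- bonds[sel, , drop = FALSE]
    bonds$i <- map[bonds$i]; bonds$j <- map[bonds$j]
    atoms <- atoms[keep, , drop = FALSE]
  }
  molecule_graph(atoms, bonds, name = name, validate = FALSE)
}
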