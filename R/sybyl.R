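#' Supported SYBYL atom types
#'
#' The closed set of SYBYL chemical types supported for ligand atoms: carbon
#' (C.1, C.2, C.3, C.ar, C.cat), nitrogen (N.1, N.2, N.3, N.4, N.am, N.ar,
#' N.pl3), oxygen (O.2, O.3, O.co2), phosphorus (P.3), sulfur (S.2, S.3, S.O,
#' S.O2) and the halogens (Br, Cl, F, I). Molecules containing atoms that do
#' not map onto one of these types are rejected at input.
#'
#' @return Character vector of the 24 supported SYBYL type codes.
#' @export
sybyl_types <- function() {
  c("C.1", "C.2", "C.3", "C.ar", "C.cat",
    "N.1", "N.2", "N.3", "N.4", "N.am", "N.ar", "N.pl3",
    "O.2", "O.3", "O.co2",
    "P.3",
    "S.2", "S.3", "S.O", "S.O2",
    "Br", "Cl", "F", "I")
}

#' @noRd
sybyl_element <- function(code) {
  sub("\\..*$", "", code)
}

#' @noRd
is_supported_sybyl <- function(code) {
  code %in% sybyl_types()
}

# Standard atomic weights for the supported elements (plus hydrogen).
.ATOMIC_WEIGHTS <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, P = 30.974,
  S = 32.06, F = 18.998, Cl = 35.45, Br = 79.904, I = 126.904
)

# Allowed total valences per element; charges shift the nitrogen/oxygen
# targets (N+ is tetravalent, O- is monovalent). S and P take the smallest
# listed valence that accommodates the existing bond orders.
.ELEMENT_VALENCES <- list(
  C = 4L, N = 3L, O = 2L, P = c(3L, 5L), S = c(2L, 4L, 6L),
  F = 1L, Cl = 1L, Br = 1L, I = 1L
)

#' Implicit hydrogen count for a heavy atom
#'
#' Number of hydrogens needed to fill an atom's valence given the sum of its
#' heavy-atom bond orders and its formal charge. Elements with several allowed
#' valences (S, P) use the smallest one that accommodates the existing bonds.
#'
#' @param element Element symbol.
#' @param charge Formal charge.
#' @param bondsum Sum of bond orders to heavy-atom neighbours.
#' @return Non-negative integer hydrogen count.
#' @keywords internal
implicit_hydrogens <- function(element, charge, bondsum) {
  vals <- .ELEMENT_VALENCES[[element]]
  if (is.null(vals)) {
    stop("unsupported element: ", element, call. = FALSE)
  }
  vals <- vals + as.integer(charge) * switch(element, N = 1L, O = 1L, 0L)
  vals <- vals[vals >= bondsum]
  if (length(vals) == 0L) {
    stop("valence overflow on ", element, " (bond order sum ", bondsum, ")",
         call. = FALSE)
  }
  as.integer(min(vals) - bondsum)
}
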