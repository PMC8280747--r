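#' Van der Waals radii and atomic masses
#'
#' The built-in radii are the Bondi set for the elements that occur in
#' thiolate-coated metal nanoparticle systems (C 1.70, N 1.55, O 1.52,
#' S 1.80, H 1.20, Au 1.66 angstrom, plus a few common ions).  Both tables
#' can be extended or overridden per element, and [load_structure()] also
#' accepts per-atom radius overrides.
#'
#' @format Named numeric vectors, angstrom (radii) and g/mol (masses).
#' @name element_tables
NULL

.bondi_radii <- c(
  H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
  F = 1.47, Cl = 1.75, Br = 1.85, I = 1.98,
  Au = 1.66, Ag = 1.72, Na = 2.27, K = 2.75, Cs = 3.43, Mg = 1.73, Zn = 1.39
)

.atomic_masses <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06, P = 30.974,
  F = 18.998, Cl = 35.45, Br = 79.904, I = 126.904,
  Au = 196.967, Ag = 107.868, Na = 22.990, K = 39.098, Cs = 132.905,
  Mg = 24.305, Zn = 65.38
)

#' Look up van der Waals radii for element symbols
#'
#' @param elements Character vector of element symbols (case normalised).
#' @param overrides Optional named numeric vector of per-element radius
#'   overrides, angstrom.
#' @param strict Error on unknown elements (default) rather than returning
#'   `NA`.
#' @return Numeric vector of radii, angstrom.
#' @export
#' @examples
#' vdw_radii(c("C", "Au"))
vdw_radii <- function(elements, overrides = NULL, strict = TRUE) {
  tab <- .bondi_radii
  if (!is.null(overrides)) {
    stopifnot(is.numeric(overrides), !is.null(names(overrides)))
    tab[normalize_element(names(overrides))] <- unname(overrides)
  }
  el <- normalize_element(elements)
  r <- unname(tab[el])
  if (strict && anyNA(r)) {
    bad <- unique(el[is.na(r)])
    abort(paste0(
      "No van der Waals radius for element(s): ", paste(bad, collapse = ", "),
      ". Supply `radius_overrides`."
    ))
  }
  r
}

#' @rdname vdw_radii
#' @export
atomic_masses <- function(elements, strict = TRUE) {
  el <- normalize_element(elements)
  m <- unname(.atomic_masses[el])
  if (strict && anyNA(m)) {
    bad <- unique(el[is.na(m)])
    abort(paste0("No atomic mass for element(s): ", paste(bad, collapse = ", ")))
  }
  m
}

# "AU"/"au" -> "Au", "c" -> "C"
normalize_element <- function(x) {
  x <- trimws(as.character(x))
  paste0(toupper(substr(x, 1, 1)), tolower(substr(x, 2, nchar(x))))
}
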