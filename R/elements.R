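# Element lookup tables: atomic numbers and van der Waals radii.
# Radii are the Bondi set (with the later main-group extensions for the
# few elements Bondi did not tabulate), stored in angstrom and converted
# to bohr on lookup.

BOHR_PER_ANGSTROM <- 1.8897261246

.element_numbers <- c(
  H = 1, He = 2, Li = 3, Be = 4, B = 5, C = 6, N = 7, O = 8, F = 9,
  Ne = 10, Na = 11, Mg = 12, Al = 13, Si = 14, P = 15, S = 16, Cl = 17,
  Ar = 18, K = 19, Ca = 20, Ga = 31, Ge = 32, As = 33, Se = 34, Br = 35,
  Kr = 36, Rb = 37, Sr = 38, In = 49, Sn = 50, Sb = 51, Te = 52, I = 53,
  Xe = 54, Cs = 55, Ba = 56, Tl = 81, Pb = 82, Bi = 83)

.bondi_radii_angstrom <- c(
  H = 1.20, He = 1.40, Li = 1.82, Be = 1.53, B = 1.92, C = 1.70,
  N = 1.55, O = 1.52, F = 1.47, Ne = 1.54, Na = 2.27, Mg = 1.73,
  Al = 1.84, Si = 2.10, P = 1.80, S = 1.80, Cl = 1.75, Ar = 1.88,
  K = 2.75, Ca = 2.31, Ga = 1.87, Ge = 2.11, As = 1.85, Se = 1.90,
  Br = 1.85, Kr = 2.02, Rb = 3.03, Sr = 2.49, In = 1.93, Sn = 2.17,
  Sb = 2.06, Te = 2.06, I = 1.98, Xe = 2.16, Cs = 3.43, Ba = 2.68,
  Tl = 1.96, Pb = 2.02, Bi = 2.07)

#' Atomic number of an element symbol
#'
#' @param element Character vector of element symbols (e.g. `"O"`).
#' @return Integer atomic numbers.
#' @export
atomic_number <- function(element) {
  z <- .element_numbers[element]
  if (anyNA(z))
    stop("unknown element symbol(s): ",
         paste(unique(element[is.na(z)]), collapse = ", "))
  as.integer(z)
}

#' Van der Waals radius of an element
#'
#' Bondi radii, returned in bohr. Per-element overrides replace the
#' tabulated value.
#'
#' @param element Character vector of element symbols.
#' @param overrides Optional named numeric vector of radii in bohr,
#'   names are element symbols.
#' @return Numeric radii in bohr.
#' @export
vdw_radius <- function(element, overrides = NULL) {
  r <- .bondi_radii_angstrom[element] * BOHR_PER_ANGSTROM
  if (!is.null(overrides)) {
    hit <- element %in% names(overrides)
    r[hit] <- overrides[element[hit]]
  }
  if (anyNA(r))
    stop("no van der Waals radius for element(s): ",
         paste(unique(element[is.na(r)]), collapse = ", "),
         "; supply one via the radius overrides")
  unname(r)
}
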