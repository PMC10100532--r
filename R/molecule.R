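# Molecules as classical charge models: element symbols, positions in
# bohr, per-atom charges (e) and Gaussian smearing widths (bohr). The
# charge density they generate is a sum of normalized Gaussians, a
# classical stand-in for a quantum charge density.

#' Construct a molecule
#'
#' @param element Character vector of element symbols.
#' @param position n x 3 numeric matrix of coordinates in bohr.
#' @param charge Per-atom charge in e; defaults to the formal nuclear
#'   charge of each element.
#' @param width Gaussian smearing width in bohr (default 0.4, resolvable
#'   at the default 0.2 bohr grid spacing).
#' @return Object of class `gpes_molecule`: a data frame with columns
#'   `element`, `x`, `y`, `z`, `charge`, `width`.
#' @export
molecule <- function(element, position, charge = NULL, width = 0.4) {
  position <- matrix(as.numeric(position), ncol = 3)
  stopifnot(nrow(position) == length(element))
  if (!all(is.finite(position))) stop("atom positions must be finite")
  if (is.null(charge)) charge <- as.numeric(atomic_number(element))
  charge <- rep_len(as.numeric(charge), length(element))
  width <- rep_len(as.numeric(width), length(element))
  if (any(width <= 0)) stop("Gaussian smearing widths must be positive")
  structure(
    data.frame(element = element, x = position[, 1], y = position[, 2],
               z = position[, 3], charge = charge, width = width,
               stringsAsFactors = FALSE),
    class = c("gpes_molecule", "data.frame"))
}

atom_positions <- function(mol) cbind(mol$x, mol$y, mol$z)

#' Read a molecule from an XYZ file
#'
#' Standard XYZ layout: an atom-count line, a comment line, then one
#' `El x y z` line per atom. An optional 5th column supplies per-atom
#' charges; atoms without one get the formal nuclear charge of their
#' element. Coordinates are converted to bohr.
#'
#' @param path Path to the XYZ file.
#' @param units Unit of the coordinates in the file: `"angstrom"`
#'   (the XYZ convention, default) or `"bohr"`.
#' @param width Gaussian smearing width assigned to every atom (bohr).
#' @return A [molecule()].
#' @export
read_xyz <- function(path, units = c("angstrom", "bohr"), width = 0.4) {
  units <- match.arg(units)
  if (!file.exists(path)) stop("XYZ file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  if (length(lines) < 1 || !grepl("^\\s*\\d+\\s*$", lines[1]))
    stop("XYZ parse error at line 1: expected the atom count")
  n <- as.integer(trimws(lines[1]))
  if (n < 1) stop("XYZ parse error at line 1: atom count must be positive")
  if (length(lines) < n + 2)
    stop(sprintf("XYZ parse error: %d atom lines declared, %d present",
                 n, max(0L, length(lines) - 2L)))
  el <- character(n); pos <- matrix(NA_real_, n, 3); q <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    lineno <- i + 2L
    tok <- strsplit(trimws(lines[lineno]), "\\s+")[[1]]
    if (length(tok) < 4)
      stop(sprintf("XYZ parse error at line %d: need 'El x y z'", lineno))
    el[i] <- tok[1]
    xyz <- suppressWarnings(as.numeric(tok[2:4]))
    if (anyNA(xyz))
      stop(sprintf("XYZ parse error at line %d: non-numeric coordinate",
                   lineno))
    pos[i, ] <- xyz
    if (length(tok) >= 5) {
      qi <- suppressWarnings(as.numeric(tok[5]))
      if (is.na(qi))
        stop(sprintf("XYZ parse error at line %d: non-numeric charge",
                     lineno))
      q[i] <- qi
    }
  }
  if (units == "angstrom") pos <- pos * BOHR_PER_ANGSTROM
  charge <- ifelse(is.na(q), as.numeric(atomic_number(el)), q)
  molecule(el, pos, charge = charge, width = width)
}
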