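# Gaussian cube volumetric I/O. The de-facto standard: all quantities in
# atomic units, axis records give node counts and (diagonal) cell
# vectors, atom records carry Z and nuclear charge, values are written
# z-fastest, six per line. Only the positive-natoms (scalar field)
# dialect is supported; orbital cubes (negative natoms) are rejected.

#' Write a scalar field to a Gaussian cube file
#'
#' @param f A [scalar_field()].
#' @param mol The [molecule()] to embed in the header (may have 0 atoms
#'   via `mol = NULL`, in which case a dummy empty header is written).
#' @param path Output path.
#' @param comment Two header comment lines.
#' @export
write_cube <- function(f, mol, path,
                       comment = c("gpes scalar field", "atomic units")) {
  g <- f$grid
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(comment[1:2], con)
  natoms <- if (is.null(mol)) 0L else nrow(mol)
  writeLines(sprintf("%5d %11.6f %11.6f %11.6f", natoms,
                     g$origin[1], g$origin[2], g$origin[3]), con)
  for (k in 1:3) {
    v <- c(0, 0, 0); v[k] <- g$spacing
    writeLines(sprintf("%5d %11.6f %11.6f %11.6f", g$shape[k],
                       v[1], v[2], v[3]), con)
  }
  if (natoms > 0) {
    z <- atomic_number(mol$element)
    writeLines(sprintf("%5d %11.6f %11.6f %11.6f %11.6f", z, mol$charge,
                       mol$x, mol$y, mol$z), con)
  }
  # z-fastest ordering: loop x slowest, write runs of values along z
  vals <- f$values
  for (i in seq_len(g$shape[1])) {
    for (j in seq_len(g$shape[2])) {
      row <- vals[i, j, ]
      lines <- tapply(sprintf("%13.5E", row),
                      (seq_along(row) - 1L) %/% 6L, paste, collapse = " ")
      writeLines(unlist(lines), con)
    }
  }
  invisible(path)
}

#' Read a Gaussian cube file
#'
#' @param path Path to a cube file written in the scalar-field dialect
#'   (positive atom count, diagonal axis vectors).
#' @return List with elements `field` (a [scalar_field()]) and
#'   `molecule` (a [molecule()], or `NULL` when the header has no atoms).
#' @export
read_cube <- function(path) {
  if (!file.exists(path)) stop("cube file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 6) stop("cube parse error: truncated header")
  toks <- function(i) strsplit(trimws(lines[i]), "\\s+")[[1]]
  hdr <- suppressWarnings(as.numeric(toks(3)))
  if (length(hdr) < 4 || anyNA(hdr))
    stop("cube parse error: malformed natoms/origin record")
  natoms <- as.integer(hdr[1])
  if (natoms < 0)
    stop("unsupported cube dialect: negative atom count (orbital cube)")
  origin <- hdr[2:4]
  shape <- integer(3); spacing <- NA_real_
  for (k in 1:3) {
    ax <- suppressWarnings(as.numeric(toks(3 + k)))
    if (length(ax) < 4 || anyNA(ax))
      stop("cube parse error: malformed axis record")
    shape[k] <- as.integer(ax[1])
    step <- ax[1 + k]
    off <- ax[2:4][-k]
    if (any(abs(off) > 1e-12))
      stop("unsupported cube dialect: non-diagonal axis vectors")
    if (is.na(spacing)) spacing <- step
    else if (abs(step - spacing) > 1e-9)
      stop("unsupported cube dialect: anisotropic spacing")
  }
  mol <- NULL
  if (natoms > 0) {
    at <- matrix(NA_real_, natoms, 5)
    for (i in seq_len(natoms)) {
      rec <- suppressWarnings(as.numeric(toks(6 + i)))
      if (length(rec) < 5 || anyNA(rec))
        stop(sprintf("cube parse error: malformed atom record %d", i))
      at[i, ] <- rec[1:5]
    }
    sym <- names(.element_numbers)[match(as.integer(at[, 1]),
                                         .element_numbers)]
    mol <- molecule(sym, at[, 3:5], charge = at[, 2])
  }
  raw <- suppressWarnings(as.numeric(unlist(
    strsplit(trimws(lines[(7 + natoms):length(lines)]), "\\s+"))))
  raw <- raw[!is.na(raw)]
  if (length(raw) != prod(shape))
    stop(sprintf("cube parse error: %d values expected, %d found",
                 prod(shape), length(raw)))
  # file order is z-fastest; R arrays are x-fastest
  vals <- aperm(array(raw, dim = rev(shape)), c(3, 2, 1))
  list(field = scalar_field(uniform_grid(origin, spacing, shape), vals),
       molecule = mol)
}
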