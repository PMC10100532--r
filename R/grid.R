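# Uniform Cartesian grids and scalar/vector fields sampled on them.
# All lengths are in bohr, energies in hartree; unit conversion happens
# only in the I/O layer (read_xyz, cube files).

#' Uniform Cartesian grid
#'
#' A regular, isotropic grid over an axis-aligned box. Node `(i, j, k)`
#' (1-based) sits at `origin + (i-1, j-1, k-1) * spacing`.
#'
#' @param origin Numeric length-3, position of the first node (bohr).
#' @param spacing Positive scalar grid step (bohr), identical on all axes.
#' @param shape Integer length-3, number of nodes per axis (each >= 8).
#' @return An object of class `uniform_grid` with fields `origin`,
#'   `spacing`, `shape`.
#' @examples
#' g <- uniform_grid(c(-4, -4, -4), 0.5, c(17, 17, 17))
#' @export
uniform_grid <- function(origin, spacing, shape) {
  origin <- as.numeric(origin)
  shape <- as.integer(shape)
  stopifnot(length(origin) == 3L, length(shape) == 3L)
  if (!is.finite(spacing) || spacing <= 0)
    stop("grid spacing must be a positive finite scalar")
  if (any(shape < 8L))
    stop("grid shape must be at least 8 nodes along every axis")
  structure(list(origin = origin, spacing = spacing, shape = shape),
            class = "uniform_grid")
}

#' @export
print.uniform_grid <- function(x, ...) {
  hi <- x$origin + (x$shape - 1L) * x$spacing
  cat(sprintf("uniform_grid: %d x %d x %d nodes, h = %g bohr\n",
              x$shape[1], x$shape[2], x$shape[3], x$spacing))
  cat(sprintf("  box [%.3f, %.3f] x [%.3f, %.3f] x [%.3f, %.3f] bohr\n",
              x$origin[1], hi[1], x$origin[2], hi[2], x$origin[3], hi[3]))
  invisible(x)
}

#' Node coordinates along each axis
#'
#' @param grid A [uniform_grid()].
#' @return List with numeric vectors `x`, `y`, `z` of node coordinates.
#' @export
grid_axes <- function(grid) {
  list(x = grid$origin[1] + (seq_len(grid$shape[1]) - 1) * grid$spacing,
       y = grid$origin[2] + (seq_len(grid$shape[2]) - 1) * grid$spacing,
       z = grid$origin[3] + (seq_len(grid$shape[3]) - 1) * grid$spacing)
}

same_grid <- function(a, b) {
  isTRUE(all.equal(a$origin, b$origin)) &&
    isTRUE(all.equal(a$spacing, b$spacing)) &&
    identical(a$shape, b$shape)
}

check_same_grid <- function(a, b) {
  if (!same_grid(a, b)) stop("fields are defined on different grids")
  invisible(TRUE)
}

#' Construct the computational box around a set of spheres
#'
#' Axis-aligned bounding box of all sphere centers extended by each
#' sphere's radius plus `padding`, snapped outward to a whole number of
#' grid steps. The reaction potential decays as 1/r, so a padding of a
#' few bohr keeps box-truncation effects below the discretization error;
#' the default elsewhere in the package is 8 bohr.
#'
#' @param centers Numeric n x 3 matrix of sphere centers (bohr).
#' @param radii Numeric vector of sphere radii (bohr).
#' @param spacing Grid step (bohr).
#' @param padding Extra margin beyond every sphere (bohr).
#' @return A [uniform_grid()].
#' @export
grid_for_spheres <- function(centers, radii, spacing, padding = 8) {
  centers <- matrix(as.numeric(centers), ncol = 3)
  lo <- apply(centers - radii, 2, min) - padding
  hi <- apply(centers + radii, 2, max) + padding
  n <- pmax(8L, as.integer(ceiling((hi - lo) / spacing)) + 1L)
  # center the snapped box on the requested one
  slack <- ((n - 1L) * spacing - (hi - lo)) / 2
  uniform_grid(lo - slack, spacing, n)
}

#' Scalar field on a uniform grid
#'
#' @param grid A [uniform_grid()].
#' @param values Numeric array with `dim == grid$shape`; finite everywhere.
#' @return Object of class `scalar_field` with fields `grid`, `values`.
#' @export
scalar_field <- function(grid, values) {
  values <- as.array(values)
  if (!identical(as.integer(dim(values)), grid$shape))
    stop("values array does not match the grid shape")
  if (!all(is.finite(values)))
    stop("scalar field contains non-finite values")
  structure(list(grid = grid, values = values), class = "scalar_field")
}

#' Vector field on a uniform grid
#'
#' Stored as three scalar component arrays `vx`, `vy`, `vz`.
#'
#' @param grid A [uniform_grid()].
#' @param vx,vy,vz Component arrays, each with `dim == grid$shape`.
#' @export
vector_field <- function(grid, vx, vy, vz) {
  for (v in list(vx, vy, vz)) {
    if (!identical(as.integer(dim(v)), grid$shape))
      stop("component array does not match the grid shape")
    if (!all(is.finite(v))) stop("vector field contains non-finite values")
  }
  structure(list(grid = grid, vx = vx, vy = vy, vz = vz),
            class = "vector_field")
}

#' @export
print.scalar_field <- function(x, ...) {
  cat(sprintf("scalar_field on %d x %d x %d grid (h = %g): range [%g, %g]\n",
              x$grid$shape[1], x$grid$shape[2], x$grid$shape[3],
              x$grid$spacing, min(x$values), max(x$values)))
  invisible(x)
}

#' Riemann-sum integral of a scalar field
#'
#' `sum(values) * h^3`, the midpoint rule on the uniform grid.
#'
#' @param f A [scalar_field()].
#' @return Scalar integral value.
#' @export
integrate_field <- function(f) {
  sum(f$values) * f$grid$spacing^3
}

#' L2 inner product of two scalar fields
#'
#' `integral(f * g)` by the Riemann sum; symmetric and bilinear.
#'
#' @param f,g Scalar fields on the same grid.
#' @export
inner_product <- function(f, g) {
  check_same_grid(f$grid, g$grid)
  sum(f$values * g$values) * f$grid$spacing^3
}

#' L2 norm of a scalar field
#'
#' `sqrt(integral(f^2))`; the norm used for SCRF convergence checks.
#'
#' @param f A [scalar_field()].
#' @export
field_norm <- function(f) {
  sqrt(sum(f$values^2)) * sqrt(f$grid$spacing^3)
}

# norm of a raw values array given the spacing (internal hot path)
values_norm <- function(values, h) sqrt(sum(values^2) * h^3)

# one-axis finite difference: central in the interior (second order),
# one-sided first order at the two faces
axis_derivative <- function(v, axis, h) {
  n <- dim(v)[axis]
  d <- array(0, dim(v))
  if (axis == 1L) {
    d[2:(n - 1), , ] <- (v[3:n, , , drop = FALSE] -
                         v[1:(n - 2), , , drop = FALSE]) / (2 * h)
    d[1, , ] <- (v[2, , ] - v[1, , ]) / h
    d[n, , ] <- (v[n, , ] - v[n - 1, , ]) / h
  } else if (axis == 2L) {
    d[, 2:(n - 1), ] <- (v[, 3:n, , drop = FALSE] -
                         v[, 1:(n - 2), , drop = FALSE]) / (2 * h)
    d[, 1, ] <- (v[, 2, ] - v[, 1, ]) / h
    d[, n, ] <- (v[, n, ] - v[, n - 1, ]) / h
  } else {
    d[, , 2:(n - 1)] <- (v[, , 3:n, drop = FALSE] -
                         v[, , 1:(n - 2), drop = FALSE]) / (2 * h)
    d[, , 1] <- (v[, , 2] - v[, , 1]) / h
    d[, , n] <- (v[, , n] - v[, , n - 1]) / h
  }
  d
}

#' Gradient of a scalar field by finite differences
#'
#' Second-order central differences at interior nodes, first-order
#' one-sided stencils on the box faces. Exact at interior nodes for
#' fields affine in the coordinates.
#'
#' @param f A [scalar_field()].
#' @return A [vector_field()].
#' @export
gradient_field <- function(f) {
  h <- f$grid$spacing
  vector_field(f$grid,
               axis_derivative(f$values, 1L, h),
               axis_derivative(f$values, 2L, h),
               axis_derivative(f$values, 3L, h))
}

# squared distances |r - c|^2 from every grid node to a point, as an array
grid_dist2 <- function(grid, center) {
  ax <- grid_axes(grid)
  dx2 <- (ax$x - center[1])^2
  dy2 <- (ax$y - center[2])^2
  dz2 <- (ax$z - center[3])^2
  outer(outer(dx2, dy2, `+`), dz2, `+`)
}
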