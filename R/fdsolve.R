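# Independent direct solver for the generalized Poisson equation:
# a 7-point flux-conservative finite-difference discretization of
#   div(eps grad V) = -4 pi rho
# with Dirichlet boundary values from a screened multipole expansion,
# assembled as one sparse symmetric system and solved directly. Shares
# nothing with the SCRF/convolution path, so it serves as an oracle for
# the converged reaction potential on small grids.

# screened monopole + dipole potential of rho evaluated at points
multipole_potential <- function(rho, px, py, pz, eps_screen) {
  h3 <- rho$grid$spacing^3
  ax <- grid_axes(rho$grid)
  n <- rho$grid$shape
  v <- rho$values
  q <- sum(v) * h3
  # charge centroid (monopole center); box center for a neutral source
  wx <- sum(slice_sums(v, 1L) * ax$x) * h3
  wy <- sum(slice_sums(v, 2L) * ax$y) * h3
  wz <- sum(slice_sums(v, 3L) * ax$z) * h3
  ctr <- if (abs(q) > 1e-12) c(wx, wy, wz) / q
         else rho$grid$origin + (n - 1) * rho$grid$spacing / 2
  p <- c(wx, wy, wz) - q * ctr
  dx <- px - ctr[1]; dy <- py - ctr[2]; dz <- pz - ctr[3]
  r2 <- dx^2 + dy^2 + dz^2
  r <- sqrt(r2)
  (q / r + (p[1] * dx + p[2] * dy + p[3] * dz) / (r2 * r)) / eps_screen
}

# sum over all but one axis -> marginal along that axis
slice_sums <- function(v, axis) apply(v, axis, sum)

# assemble and solve the Dirichlet problem; eps_fun(px, py, pz) samples
# the permittivity at arbitrary points (cell faces), bc values come
# from multipole_potential screened by eps_screen
fd_dirichlet_solve <- function(rho, eps_fun, eps_screen) {
  g <- rho$grid
  n <- g$shape
  h <- g$spacing
  ax <- grid_axes(g)
  ni <- n - 2L                          # interior nodes per axis
  idx <- function(i, j, k) (i - 1L) + ni[1] * ((j - 1L) + ni[2] * (k - 1L)) + 1L
  # interior node coordinates
  ix <- ax$x[2:(n[1] - 1)]; iy <- ax$y[2:(n[2] - 1)]; iz <- ax$z[2:(n[3] - 1)]
  I <- array(rep(seq_len(ni[1]), times = ni[2] * ni[3]), dim = ni)
  J <- array(rep(rep(seq_len(ni[2]), each = ni[1]), times = ni[3]), dim = ni)
  K <- array(rep(seq_len(ni[3]), each = ni[1] * ni[2]), dim = ni)
  px <- ix[I]; py <- iy[J]; pz <- iz[K]
  rows <- integer(0); cols <- integer(0); vals <- numeric(0)
  diag_acc <- array(0, ni)
  b <- array(4 * pi * rho$values[2:(n[1] - 1), 2:(n[2] - 1), 2:(n[3] - 1)],
             dim = ni)
  center <- idx(I, J, K)
  offs <- list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
               c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  for (o in offs) {
    # permittivity at the face midpoint between node and neighbor
    fpx <- px + o[1] * h / 2; fpy <- py + o[2] * h / 2; fpz <- pz + o[3] * h / 2
    ef <- eps_fun(fpx, fpy, fpz) / h^2
    diag_acc <- diag_acc + ef
    In <- I + o[1]; Jn <- J + o[2]; Kn <- K + o[3]
    inside <- In >= 1 & In <= ni[1] & Jn >= 1 & Jn <= ni[2] &
      Kn >= 1 & Kn <= ni[3]
    rows <- c(rows, center[inside])
    cols <- c(cols, idx(pmax(In, 1L), pmax(Jn, 1L), pmax(Kn, 1L))[inside])
    vals <- c(vals, -ef[inside])
    if (any(!inside)) {
      # neighbor is a Dirichlet boundary node: move it to the RHS
      bx <- px + o[1] * h; by <- py + o[2] * h; bz <- pz + o[3] * h
      vb <- multipole_potential(rho, bx[!inside], by[!inside], bz[!inside],
                                eps_screen)
      b[!inside] <- b[!inside] + ef[!inside] * vb
    }
  }
  N <- prod(ni)
  A <- Matrix::sparseMatrix(
    i = c(seq_len(N), rows), j = c(seq_len(N), cols),
    x = c(as.numeric(diag_acc), vals), dims = c(N, N))
  # the operator is symmetric positive definite: use a CHOLMOD Cholesky
  ch <- Matrix::Cholesky(Matrix::forceSymmetric(A), LDL = FALSE)
  sol <- as.numeric(Matrix::solve(ch, as.numeric(b), system = "A"))
  # re-attach the boundary shell with its Dirichlet values
  V <- array(0, n)
  V[2:(n[1] - 1), 2:(n[2] - 1), 2:(n[3] - 1)] <- array(sol, ni)
  full_I <- array(rep(seq_len(n[1]), times = n[2] * n[3]), dim = n)
  full_J <- array(rep(rep(seq_len(n[2]), each = n[1]), times = n[3]), dim = n)
  full_K <- array(rep(seq_len(n[3]), each = n[1] * n[2]), dim = n)
  bdry <- full_I == 1 | full_I == n[1] | full_J == 1 | full_J == n[2] |
    full_K == 1 | full_K == n[3]
  V[bdry] <- multipole_potential(rho, ax$x[full_I[bdry]], ax$y[full_J[bdry]],
                                 ax$z[full_K[bdry]], eps_screen)
  scalar_field(g, V)
}

#' Direct finite-difference solution of the generalized Poisson equation
#'
#' Independent oracle for [solve_reaction_potential()]: solves
#' `div(eps grad V) = -4 pi rho` by a flux-form 7-point stencil with
#' face-sampled permittivities and screened monopole+dipole Dirichlet
#' values on the box faces, then subtracts the identically discretized
#' vacuum solve (`eps = 1`, unscreened boundary values) to obtain the
#' reaction potential. Cost grows as the cube of the node count; meant
#' for grids around 32^3.
#'
#' @param rho Solute density ([scalar_field()]).
#' @param model A [dielectric_model()].
#' @return List with `V` (total potential), `V_rho` (vacuum potential)
#'   and `V_R = V - V_rho`, all [scalar_field()]s.
#' @export
solve_gpe_fd <- function(rho, model) {
  if (prod(rho$grid$shape) > 40^3)
    stop("solve_gpe_fd is a small-grid oracle; refuse > 40^3 nodes")
  V <- fd_dirichlet_solve(
    rho, function(px, py, pz) permittivity_at(model, px, py, pz),
    eps_screen = model$eps_out)
  V0 <- fd_dirichlet_solve(
    rho, function(px, py, pz) rep(1, length(px)), eps_screen = 1)
  list(V = V, V_rho = V0,
       V_R = scalar_field(rho$grid, V$values - V0$values))
}
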