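# Shared builders for small, well-resolved test systems. Solves are
# cached per session so several test files can reuse one SCRF result.

.solve_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .solve_cache))
    assign(key, force(expr), envir = .solve_cache)
  get(key, envir = .solve_cache)
}

# a Born sphere whose boundary shell is resolved (sigma = 2h)
tiny_born <- function(eps_out = 80, sigma = 0.4, spacing = 0.2, radius = 2,
                      padding = 3.4, width = 0.8, q = 1) {
  born_system(q = q, radius = radius, eps_out = eps_out, sigma = sigma,
              spacing = spacing, padding = padding, width = width)
}

tiny_born_solution <- function(eps_out = 80, delta = 1e-6) {
  key <- sprintf("born_eps%g_delta%g", eps_out, delta)
  cached(key, {
    sys <- tiny_born(eps_out = eps_out)
    sol <- solve_reaction_potential(sys$rho, sys$model,
                                    scrf_config(delta = delta))
    list(sys = sys, sol = sol,
         E = polarization_energy(sys$rho, sol$V_R))
  })
}

# three-sphere toy cavity (overlapping) used by cavity/dielectric tests
toy_cavity <- function(sigma = 0.3) {
  cavity(rbind(c(0, 0, 0), c(1.5, 0, 0), c(0.4, 1.1, -0.3)),
         c(2.0, 1.6, 1.2),
         cavity_params(alpha = 1, beta = 0, sigma = sigma),
         parametrize = FALSE)
}

toy_grid <- function(spacing = 0.25, half = 4.5) {
  n <- round(2 * half / spacing) + 1
  uniform_grid(rep(-half, 3), spacing, rep(n, 3))
}

water_molecule <- function(width = 0.4) {
  read_xyz(system.file("extdata", "water.xyz", package = "gpes"),
           width = width)
}

grid_dist2_test <- function(grid, c0) gpes:::grid_dist2(grid, c0)

gpes_erf <- function(x) 2 * pnorm(x * sqrt(2)) - 1

atom_positions_test <- function(mol) cbind(mol$x, mol$y, mol$z)

# random smooth density: a few random Gaussians inside the box
random_density <- function(grid, natoms = 4, seed = 1) {
  set.seed(seed)
  lo <- grid$origin + 0.3 * (grid$shape - 1) * grid$spacing
  hi <- grid$origin + 0.7 * (grid$shape - 1) * grid$spacing
  pos <- cbind(runif(natoms, lo[1], hi[1]), runif(natoms, lo[2], hi[2]),
               runif(natoms, lo[3], hi[3]))
  mol <- molecule(rep("H", natoms), pos, charge = runif(natoms, -1, 1),
                  width = runif(natoms, 3, 5) * grid$spacing)
  gaussian_density(mol, grid)
}
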