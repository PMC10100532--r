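# Solute densities, polarization energy, analytic references, and the
# end-to-end workflow.

test_that("gaussian_density integrates to the molecular charge", {
  g <- uniform_grid(rep(-5, 3), 0.25, rep(41, 3))
  one <- molecule("H", matrix(0, 1, 3), charge = 1, width = 0.8)
  expect_equal(integrate_field(gaussian_density(one, g)), 1,
               tolerance = 1e-6)
  # +/- pair is neutral
  pair <- molecule(c("H", "H"), rbind(c(-1, 0, 0), c(1, 0, 0)),
                   charge = c(1, -1), width = 0.8)
  expect_lt(abs(integrate_field(gaussian_density(pair, g))), 1e-6)
  # additivity over atoms at machine precision
  a <- gaussian_density(pair[1, ], g)
  b <- gaussian_density(pair[2, ], g)
  expect_equal(gaussian_density(pair, g)$values, a$values + b$values,
               tolerance = 1e-14)
  # unresolvable width is refused with advice
  expect_error(gaussian_density(molecule("H", matrix(0, 1, 3), width = 0.3), g),
               "spacing")
})

test_that("polarization energy is the half inner product with quadratic charge scaling", {
  g <- uniform_grid(rep(-3, 3), 0.5, rep(13, 3))
  rho <- random_density(g, seed = 2)
  zero <- scalar_field(g, array(0, g$shape))
  expect_equal(polarization_energy(rho, zero), 0)
  vr <- random_density(g, seed = 3)
  expect_equal(polarization_energy(rho, vr),
               0.5 * inner_product(rho, vr))
  # doubling q quadruples |E_pol| under linear response: V_R also doubles
  expect_equal(polarization_energy(scalar_field(g, 2 * rho$values),
                                   scalar_field(g, 2 * vr$values)),
               4 * polarization_energy(rho, vr), tolerance = 1e-12)
})

test_that("Born and Onsager sharp-cavity references evaluate their closed forms", {
  expect_equal(born_reference(1, 2, 80), -0.246875)
  expect_equal(born_reference(1, 3, 80), -(1 - 1 / 80) / 6)
  expect_equal(born_reference(2, 2, 1), 0)
  expect_equal(born_reference(1, 1, 80), 2 * born_reference(1, 2, 80))
  expect_equal(onsager_reference(1, 3, 80), -(79 / 161) / 27)
  expect_equal(onsager_reference(1, 3, 1), 0)
  expect_equal(onsager_reference(-1.3, 3, 80), onsager_reference(1.3, 3, 80))
})

test_that("the exact diffuse Born quadrature converges to the sharp Born limit", {
  sharp <- born_reference(1, 3, 80)
  errs <- vapply(c(0.4, 0.2, 0.1, 0.05, 0.01),
                 function(s) abs(born_exact_diffuse(1, 3, 80, s) - sharp),
                 numeric(1))
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[5] / abs(sharp), 0.003)
  # frozen value from the quadrature at the default-like sigma
  expect_equal(born_exact_diffuse(1, 3, 80, 0.1), -0.168599,
               tolerance = 1e-4)
})

test_that("grid solver matches the exact diffuse-Born energy when the shell is resolved", {
  bs <- tiny_born_solution()     # sigma = 0.4 = 2h, R = 2, w = 0.8
  # exact 1D oracle for the *smeared* charge: Gauss's law gives
  # V_R(r) = -q int_r^inf (1 - 1/eps(s)) / s^2 ds, and the energy
  # samples it with the Gaussian weight 4 pi r^2 rho(r) / 2
  R <- 2; eps <- 80; sg <- 0.4; w <- 0.8
  r <- seq(1e-4, R + 12 * sg, length.out = 200001)
  dr <- r[2] - r[1]
  epsr <- exp((1 - sphere_boundary(r - R, sg)) * log(eps))
  y <- (1 - 1 / epsr) / r^2
  tail <- (1 - 1 / eps) / max(r)
  VR <- -(rev(cumsum(rev(y))) * dr + tail)      # V_R(r), point-charge source
  rho_r <- (pi * w^2)^(-1.5) * exp(-(r / w)^2)
  exact <- 0.5 * sum(4 * pi * r^2 * rho_r * VR) * dr
  expect_equal(bs$E, exact, tolerance = 0.005)
})

test_that("run_solvation is monotone in eps_out and exact in the vacuum limit", {
  mol <- molecule("H", matrix(0, 1, 3), charge = 1, width = 0.8)
  run1 <- function(eps) {
    sys <- tiny_born(eps_out = eps, sigma = 0.3, spacing = 0.3, padding = 3)
    sol <- solve_reaction_potential(sys$rho, sys$model)
    polarization_energy(sys$rho, sol$V_R)
  }
  Es <- vapply(c(2, 4, 80), run1, numeric(1))
  expect_true(all(Es < 0))
  expect_true(all(diff(abs(Es)) > 0))
  expect_lt(abs(run1(1)), 1e-8)
})

test_that("run_solvation on water finishes with a negative energy and echoes parameters", {
  mol <- read_xyz(system.file("extdata", "water_tip3p.xyz", package = "gpes"),
                  width = 0.6)
  res <- run_solvation(mol, eps_out = 80, spacing = 0.3, padding = 4)
  expect_s3_class(res, "solvation_result")
  expect_lt(res$E_pol, 0)
  expect_equal(res$parameters$alpha, 1.1)
  expect_equal(res$parameters$beta, 0.5)
  expect_equal(res$parameters$sigma, 0.2)
  js <- jsonlite::fromJSON(solvation_json(res))
  expect_equal(js$E_pol, res$E_pol, tolerance = 1e-12)
  expect_length(js$trace, res$iterations)
})

test_that("energy is translation invariant within the discretization error", {
  E_at <- function(center) {
    sys <- born_system(q = 1, radius = 2, eps_out = 80, sigma = 0.4,
                       spacing = 0.2, padding = 3.4, width = 0.8,
                       center = center)
    sol <- solve_reaction_potential(sys$rho, sys$model,
                                    scrf_config(delta = 1e-6))
    polarization_energy(sys$rho, sol$V_R)
  }
  e0 <- E_at(c(0, 0, 0))
  e1 <- E_at(c(0.1, 0.07, 0.03))   # off the node lattice
  expect_lt(abs(e1 - e0) / abs(e0), 1e-3)
})

test_that("an off-center charge polarizes the boundary more strongly (Kirkwood)", {
  E_off <- function(off) {
    sys <- born_system(q = 1, radius = 2.5, eps_out = 80, sigma = 0.3,
                       spacing = 0.25, padding = 3, width = 0.6)
    mol <- molecule("H", matrix(c(off, 0, 0), 1, 3), charge = 1, width = 0.6)
    rho <- gaussian_density(mol, sys$grid)
    sol <- solve_reaction_potential(rho, sys$model)
    polarization_energy(rho, sol$V_R)
  }
  Es <- vapply(c(0, 0.6, 1.2), E_off, numeric(1))
  expect_true(all(diff(abs(Es)) > 0))
})

test_that("energies contract under grid refinement (Cauchy check)", {
  E_h <- function(h) {
    sys <- tiny_born(sigma = 0.5, spacing = h, padding = 2.8)
    sol <- solve_reaction_potential(sys$rho, sys$model,
                                    scrf_config(delta = 1e-6))
    polarization_energy(sys$rho, sol$V_R)
  }
  E1 <- E_h(0.4); E2 <- E_h(0.2); E3 <- E_h(0.1)
  expect_gt(abs(E1 - E2), abs(E2 - E3))
})
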