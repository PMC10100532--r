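# Grid/field primitives: quadrature, inner products, finite-difference
# gradients, and the XYZ / Gaussian-cube I/O contracts.

test_that("integrate_field reproduces exact volumes and Gaussian normalization", {
  g <- uniform_grid(c(-2, -2, -2), 0.5, c(9, 9, 9))
  expect_equal(integrate_field(scalar_field(g, array(1, g$shape))),
               (9 * 0.5)^3)
  expect_equal(integrate_field(scalar_field(g, array(0, g$shape))), 0)
  # normalized 3-D Gaussian fully inside the box, spacing = width/4
  w <- 1.0
  gg <- uniform_grid(rep(-6, 3), w / 4, rep(49, 3))
  d2 <- outer(outer(grid_axes(gg)$x^2, grid_axes(gg)$y^2, `+`),
              grid_axes(gg)$z^2, `+`)
  f <- scalar_field(gg, (pi * w^2)^(-1.5) * exp(-d2 / w^2))
  expect_equal(integrate_field(f), 1, tolerance = 1e-6)
})

test_that("inner_product is symmetric, positive and matches the Gaussian overlap formula", {
  g <- uniform_grid(rep(-6, 3), 0.25, rep(49, 3))
  mk <- function(c0, w) {
    d2 <- grid_dist2_test(g, c0)
    scalar_field(g, (pi * w^2)^(-1.5) * exp(-d2 / w^2))
  }
  f1 <- mk(c(-0.7, 0.2, 0.1), 1.0)
  f2 <- mk(c(0.8, -0.3, 0.4), 1.0)
  expect_equal(inner_product(f1, f2), inner_product(f2, f1))
  expect_gte(inner_product(f1, f1), 0)
  expect_equal(inner_product(f1, scalar_field(g, array(0, g$shape))), 0)
  # closed-form overlap of two normalized Gaussians of width w:
  # (2 pi w^2)^(-3/2) exp(-d^2 / (2 w^2))
  d <- sqrt(sum((c(-0.7, 0.2, 0.1) - c(0.8, -0.3, 0.4))^2))
  exact <- (2 * pi)^(-1.5) * exp(-d^2 / 2)
  expect_equal(inner_product(f1, f2), exact, tolerance = 1e-5)
  # bilinearity
  expect_equal(inner_product(scalar_field(g, 2 * f1$values + 3 * f2$values), f2),
               2 * inner_product(f1, f2) + 3 * inner_product(f2, f2))
  expect_error(inner_product(f1, scalar_field(
    uniform_grid(rep(0, 3), 0.25, rep(49, 3)), f2$values)), "different grids")
})

test_that("gradient is exact on affine fields and second order on smooth ones", {
  g <- uniform_grid(rep(-1, 3), 0.25, rep(9, 3))
  ax <- grid_axes(g)
  X <- array(rep(ax$x, 81), dim = g$shape)
  Y <- array(rep(rep(ax$y, each = 9), 9), dim = g$shape)
  Z <- array(rep(ax$z, each = 81), dim = g$shape)
  gr <- gradient_field(scalar_field(g, 2 * X + 3 * Y - Z))
  int <- 2:8
  expect_equal(max(abs(gr$vx[int, int, int] - 2)), 0, tolerance = 1e-12)
  expect_equal(max(abs(gr$vy[int, int, int] - 3)), 0, tolerance = 1e-12)
  expect_equal(max(abs(gr$vz[int, int, int] + 1)), 0, tolerance = 1e-12)
  gc <- gradient_field(scalar_field(g, array(5, g$shape)))
  expect_equal(max(abs(gc$vx), abs(gc$vy), abs(gc$vz)), 0)
  # sin(kx): halving h cuts the interior error by ~4 (second order)
  k <- 2
  err_at <- function(h) {
    n <- round(2 / h) + 1
    gg <- uniform_grid(c(-1, -0.5, -0.5), h, c(n, 9, 9))
    axx <- grid_axes(gg)$x
    f <- scalar_field(gg, array(rep(sin(k * axx), 81), dim = gg$shape))
    gr <- gradient_field(f)
    exact <- array(rep(k * cos(k * axx), 81), dim = gg$shape)
    ii <- 2:(n - 1)
    max(abs((gr$vx - exact)[ii, 2:8, 2:8]))
  }
  ratio <- err_at(0.1) / err_at(0.05)
  expect_gt(ratio, 2.5)
  expect_lt(ratio, 6)
  # gradient of a sum = sum of gradients
  set.seed(7)
  a <- array(rnorm(prod(g$shape)), g$shape)
  b <- array(rnorm(prod(g$shape)), g$shape)
  gs <- gradient_field(scalar_field(g, a + b))
  ga <- gradient_field(scalar_field(g, a))
  gb <- gradient_field(scalar_field(g, b))
  expect_equal(gs$vx, ga$vx + gb$vx, tolerance = 1e-12)
})

test_that("read_xyz parses geometry, units and the optional charge column", {
  mol <- water_molecule()
  expect_s3_class(mol, "gpes_molecule")
  expect_equal(nrow(mol), 3)
  doh <- sqrt(sum((atom_positions_test(mol)[1, ] -
                   atom_positions_test(mol)[2, ])^2))
  expect_equal(doh, 0.9572 * 1.8897261246, tolerance = 1e-3)
  expect_equal(mol$charge, c(8, 1, 1))   # formal nuclear charges
  # 5th column charges
  tip <- read_xyz(system.file("extdata", "water_tip3p.xyz", package = "gpes"))
  expect_equal(tip$charge, c(-0.834, 0.417, 0.417))
  # bohr flag skips the conversion
  tmp <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("1", "one atom", "H 1.0 0.0 0.0"), tmp)
  expect_equal(read_xyz(tmp, units = "bohr")$x, 1.0)
  expect_equal(read_xyz(tmp)$x, 1.8897261246, tolerance = 1e-9)
  # malformed inputs name the offending line
  empty <- withr::local_tempfile(fileext = ".xyz")
  writeLines(character(0), empty)
  expect_error(read_xyz(empty), "line 1")
  bad <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("2", "c", "H 0 0 0", "H 0 zz 0"), bad)
  expect_error(read_xyz(bad), "line 4")
  unk <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("1", "c", "Qq 0 0 0"), unk)
  expect_error(read_xyz(unk), "element")
})

test_that("cube files round-trip geometry exactly and values to print precision", {
  g <- uniform_grid(c(-1.2, -1.1, -1.0), 0.35, c(9, 10, 11))
  set.seed(3)
  f <- scalar_field(g, array(rnorm(prod(g$shape)), g$shape))
  mol <- molecule(c("O", "H"), rbind(c(0, 0, 0), c(1.5, 0, 0)))
  tmp <- withr::local_tempfile(fileext = ".cube")
  write_cube(f, mol, tmp)
  back <- read_cube(tmp)
  expect_equal(back$field$grid$origin, g$origin, tolerance = 1e-6)
  expect_equal(back$field$grid$spacing, g$spacing, tolerance = 1e-9)
  expect_identical(back$field$grid$shape, g$shape)
  expect_lt(max(abs(back$field$values - f$values)), 1e-4)
  expect_equal(back$molecule$element, c("O", "H"))
  # header contract: natoms + origin, then three axis records
  hdr <- readLines(tmp, n = 6)
  expect_equal(as.numeric(strsplit(trimws(hdr[3]), "\\s+")[[1]])[1], 2)
  expect_equal(as.numeric(strsplit(trimws(hdr[4]), "\\s+")[[1]])[1], 9)
  # orbital-cube dialect (negative natoms) is refused explicitly
  bad <- readLines(tmp)
  bad[3] <- sub("^\\s*2", "   -2", bad[3])
  tmp2 <- withr::local_tempfile(fileext = ".cube")
  writeLines(bad, tmp2)
  expect_error(read_cube(tmp2), "dialect")
})
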