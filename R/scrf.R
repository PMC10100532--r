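# Self-consistent reaction field (SCRF): the iterative solution of the
# generalized Poisson equation
#   div(eps(r) grad V) = -4 pi rho
# for the reaction potential V_R = V - V_rho.
#
# Writing the equation in Laplacian form splits the source into the
# effective charge rho_eff = rho / eps and the polarization function
#   gamma = (1 / 4 pi) grad log eps . grad V,
# giving the fixed-point relation
#   V_R = P[ (rho_eff - rho) + gamma(V_rho + V_R) ]
# with P the free-space Poisson kernel. Each microiteration evaluates
# the four steps (total-potential assembly, gamma, kernel application,
# KAIN update) and checks the L2 norm of the accepted reaction-potential
# update against the threshold delta.

#' SCRF solver configuration
#'
#' @param delta Convergence threshold on the L2 norm of the
#'   reaction-potential update (hartree/e * bohr^{3/2}).
#' @param max_microiter Microiteration cap.
#' @param kain_history KAIN history length; 0 disables acceleration
#'   (plain, optionally damped, fixed-point iteration). Default 5, a
#'   good compromise between convergence rate and memory.
#' @param damping Plain-step damping in (0, 1]; 1 (no damping) by
#'   default, exposed for pathological permittivity contrasts.
#' @export
scrf_config <- function(delta = 1e-5, max_microiter = 100,
                        kain_history = 5, damping = 1.0) {
  stopifnot(delta > 0, max_microiter >= 1, kain_history >= 0,
            damping > 0, damping <= 1)
  structure(list(delta = delta, max_microiter = max_microiter,
                 kain_history = kain_history, damping = damping),
            class = "scrf_config")
}

#' Effective charge density
#'
#' `rho_eff = rho / eps`, the screened source of the Laplacian-form GPE.
#'
#' @param rho,eps Scalar fields on the same grid; `eps > 0` nodewise.
#' @return A [scalar_field()].
#' @export
effective_density <- function(rho, eps) {
  check_same_grid(rho$grid, eps$grid)
  if (min(eps$values) <= 0) stop("permittivity must be positive nodewise")
  scalar_field(rho$grid, rho$values / eps$values)
}

#' Polarization function
#'
#' `gamma(r) = (1 / 4 pi) grad log eps . grad V`: the induced
#' volume-charge density, supported on the dielectric boundary shell
#' where `grad log eps` is nonzero.
#'
#' @param grad_log_eps A [vector_field()].
#' @param grad_V A [vector_field()] on the same grid.
#' @return A [scalar_field()].
#' @export
polarization_function <- function(grad_log_eps, grad_V) {
  check_same_grid(grad_log_eps$grid, grad_V$grid)
  g <- (grad_log_eps$vx * grad_V$vx + grad_log_eps$vy * grad_V$vy +
        grad_log_eps$vz * grad_V$vz) / (4 * pi)
  scalar_field(grad_log_eps$grid, g)
}

scrf_failure <- function(message, trace) {
  stop(structure(class = c("gpes_scrf_error", "error", "condition"),
                 list(message = message, call = sys.call(-1),
                      trace = trace)))
}

#' Solve for the reaction potential by SCRF microiterations
#'
#' Before iterating, `rho_eff` and the vacuum potential
#' `V_rho = P[rho]` are computed once. Each microiteration assembles
#' `V = V_rho + V_R`, evaluates `gamma` from the finite-difference
#' `grad V` and the analytic `grad log eps`, applies the Poisson kernel
#' to `(rho_eff - rho) + gamma`, and takes a KAIN-accelerated update.
#' Iteration stops when the L2 norm of the accepted update drops below
#' `config$delta`.
#'
#' @param rho Solute charge density, a [scalar_field()] decaying at the
#'   box faces.
#' @param model A [dielectric_model()].
#' @param config An [scrf_config()].
#' @param guess Starting reaction potential (a [scalar_field()]), or
#'   `NULL` for the zero guess.
#' @param fields Precomputed [dielectric_fields()] (recomputed when
#'   `NULL`); pass them when solving repeatedly on one grid.
#' @param op Precomputed [poisson_operator()] for the grid, or `NULL`.
#' @return List with `V_R` (converged [scalar_field()]), `V_rho`,
#'   `iterations`, `trace` (update norms per microiteration),
#'   `converged = TRUE`.
#' @seealso [macro_driver()] for the macroiteration regimes,
#'   [gpe_residual()] for an a-posteriori check of the solution.
#' @export
solve_reaction_potential <- function(rho, model, config = scrf_config(),
                                     guess = NULL, fields = NULL,
                                     op = NULL) {
  grid <- rho$grid
  h <- grid$spacing
  if (is.null(fields)) fields <- dielectric_fields(model, grid)
  if (is.null(op)) op <- poisson_operator(grid)
  check_same_grid(fields$eps$grid, grid)
  rho_eff <- effective_density(rho, fields$eps)
  V_rho <- poisson_apply(op, rho)
  src_static <- rho_eff$values - rho$values
  homogeneous <- abs(log(model$eps_out / model$eps_in)) < .Machine$double.eps
  x <- if (is.null(guess)) array(0, grid$shape) else {
    check_same_grid(guess$grid, grid)
    guess$values
  }
  x_hist <- list()
  f_hist <- list()
  trace <- numeric(0)
  for (i in seq_len(config$max_microiter)) {
    Vtot <- scalar_field(grid, V_rho$values + x)
    gam <- polarization_function(fields$grad_log_eps, gradient_field(Vtot))
    src <- scalar_field(grid, src_static + gam$values)
    Gx <- suppressWarnings(poisson_apply(op, src))$values
    f <- Gx - x
    if (config$kain_history > 0) {
      x_hist <- c(x_hist, list(x))
      f_hist <- c(f_hist, list(f))
      if (length(x_hist) > config$kain_history) {
        x_hist <- x_hist[-1]
        f_hist <- f_hist[-1]
      }
      x_new <- kain_step(x_hist, f_hist, config$damping)
    } else {
      x_new <- x + config$damping * f
    }
    if (!all(is.finite(x_new)))
      scrf_failure("non-finite reaction-potential iterate", trace)
    upd <- values_norm(x_new - x, h)
    trace <- c(trace, upd)
    x <- x_new
    if (upd < config$delta || homogeneous)
      return(list(V_R = scalar_field(grid, x), V_rho = V_rho,
                  iterations = i, trace = trace, converged = TRUE))
  }
  scrf_failure(sprintf(
    "SCRF did not converge in %d microiterations (last update %.3e, delta %.3e)",
    config$max_microiter, trace[length(trace)], config$delta), trace)
}

#' Residual of the generalized Poisson equation
#'
#' A-posteriori check: `|| div(eps grad(V_rho + V_R)) + 4 pi rho ||`
#' relative to `|| 4 pi rho ||`, with all derivatives by central finite
#' differences. Dominated by the O(h^2) discretization error of the
#' stencils, so it shrinks under grid refinement.
#'
#' @param rho Solute density ([scalar_field()]).
#' @param V_total Total potential `V_rho + V_R` ([scalar_field()]).
#' @param eps Permittivity field ([scalar_field()]).
#' @param interior_margin Nodes to drop from each face before taking
#'   the norm (the one-sided face stencils are first order).
#' @return Relative residual (dimensionless scalar).
#' @export
gpe_residual <- function(rho, V_total, eps, interior_margin = 3L) {
  g <- gradient_field(V_total)
  fx <- eps$values * g$vx
  fy <- eps$values * g$vy
  fz <- eps$values * g$vz
  h <- rho$grid$spacing
  divv <- axis_derivative(fx, 1L, h) + axis_derivative(fy, 2L, h) +
    axis_derivative(fz, 3L, h)
  res <- divv + 4 * pi * rho$values
  n <- rho$grid$shape
  m <- interior_margin
  ii <- (1 + m):(n[1] - m); jj <- (1 + m):(n[2] - m); kk <- (1 + m):(n[3] - m)
  sqrt(sum(res[ii, jj, kk]^2) / sum((4 * pi * rho$values[ii, jj, kk])^2))
}

#' Macroiteration driver: the four SCRF convergence regimes
#'
#' Emulates the outer self-consistent-field loop that the reaction-field
#' solve is nested in: each entry of `densities` is the solute density
#' at one macroiteration, converging to the final density. Two switches
#' define four regimes:
#' guess for `V_R` — (A) zero each macroiteration, (B) the converged
#' `V_R` of the previous one; microiteration threshold — (C) fixed at
#' `base_delta`, (D) dynamic, equal to the density-update norm
#' `|rho^n - rho^(n-1)|` of the parent macroiteration (floored at
#' `base_delta` so the final solve always reaches the target
#' precision). BD is the default pairing: progressively tighter
#' thresholds exactly when the warm start makes them cheap.
#'
#' @param densities List of [scalar_field()] densities, one per
#'   macroiteration, on a common grid (update norms decreasing).
#' @param model A [dielectric_model()].
#' @param regime One of `"AC"`, `"BC"`, `"AD"`, `"BD"`.
#' @param base_delta Target (and floor) threshold.
#' @param config Base [scrf_config()]; its `delta` is overridden per
#'   macroiteration as the regime dictates.
#' @return List with `microiterations` (per macroiteration),
#'   `thresholds`, `density_updates`, `total` microiterations and the
#'   final solve's result under `final`.
#' @export
macro_driver <- function(densities, model, regime = c("BD", "AC", "BC", "AD"),
                         base_delta = 1e-5, config = scrf_config()) {
  regime <- match.arg(regime)
  stopifnot(length(densities) >= 1)
  grid <- densities[[1]]$grid
  fields <- dielectric_fields(model, grid)
  op <- poisson_operator(grid)
  h <- grid$spacing
  warm <- substr(regime, 1, 1) == "B"
  dynamic <- substr(regime, 2, 2) == "D"
  prev_vals <- array(0, grid$shape)       # zero "previous density"
  prev_VR <- NULL
  micro <- integer(0)
  thresholds <- numeric(0)
  dnorms <- numeric(0)
  res <- NULL
  for (nmac in seq_along(densities)) {
    rho <- densities[[nmac]]
    check_same_grid(rho$grid, grid)
    dnorm <- values_norm(rho$values - prev_vals, h)
    # the dynamic threshold needs a parent density update, so the first
    # macroiteration always runs at base_delta (all regimes coincide on
    # a single-entry sequence)
    delta_n <- if (dynamic && nmac > 1) max(dnorm, base_delta)
               else base_delta
    cfg <- config
    cfg$delta <- delta_n
    guess <- if (warm) prev_VR else NULL
    res <- tryCatch(
      solve_reaction_potential(rho, model, cfg, guess = guess,
                               fields = fields, op = op),
      gpes_scrf_error = function(e)
        stop(sprintf("macroiteration %d: %s", nmac, conditionMessage(e))))
    micro <- c(micro, res$iterations)
    thresholds <- c(thresholds, delta_n)
    dnorms <- c(dnorms, dnorm)
    prev_VR <- res$V_R
    prev_vals <- rho$values
  }
  list(regime = regime, microiterations = micro, thresholds = thresholds,
       density_updates = dnorms, total = sum(micro), final = res)
}
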