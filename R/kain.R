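# Krylov-accelerated inexact Newton (KAIN) update, the DIIS/Anderson
# relative used to accelerate the SCRF fixed-point iteration.
#
# With stored iterates x_1..x_m and their fixed-point updates
# f_i = G(x_i) - x_i, the accelerated step solves the (m-1) x (m-1)
# least-squares-type system
#   A c = b,  A[i, j] = <x_i - x_m, f_j - f_m>,  b[i] = -<x_i - x_m, f_m>
# and takes
#   x_new = x_m + f_m + sum_i c_i [ (x_i - x_m) + (f_i - f_m) ].
# For an affine map G the iterates span a Krylov space, so convergence
# is exact in at most dim + 1 steps. The inner product is the plain
# elementwise sum: a constant quadrature weight (h^3) scales A and b
# identically and cancels in c.

#' One KAIN-accelerated fixed-point step
#'
#' @param x_hist List of stored iterates (numeric vectors/arrays of a
#'   common shape), oldest first, current iterate last.
#' @param f_hist List of the corresponding updates `G(x) - x`.
#' @param damping Step scale used only for the history-free plain step.
#' @return The accelerated next iterate. With a single stored pair this
#'   is the plain (damped) step `x + damping * f`. A singular history
#'   system falls back by discarding the oldest entries.
#' @export
kain_step <- function(x_hist, f_hist, damping = 1.0) {
  stopifnot(length(x_hist) == length(f_hist), length(x_hist) >= 1)
  repeat {
    m <- length(x_hist)
    xm <- x_hist[[m]]
    fm <- f_hist[[m]]
    if (m == 1) return(xm + damping * fm)
    k <- m - 1
    A <- matrix(0, k, k)
    b <- numeric(k)
    dX <- lapply(x_hist[1:k], function(x) x - xm)
    dF <- lapply(f_hist[1:k], function(f) f - fm)
    for (i in 1:k) {
      b[i] <- -sum(dX[[i]] * fm)
      for (j in 1:k) A[i, j] <- sum(dX[[i]] * dF[[j]])
    }
    coef <- tryCatch(solve(A, b), error = function(e) NULL)
    if (!is.null(coef) && all(is.finite(coef))) {
      out <- xm + fm
      for (i in 1:k) out <- out + coef[i] * (dX[[i]] + dF[[i]])
      return(out)
    }
    # degenerate system: evict the oldest pair and retry
    x_hist <- x_hist[-1]
    f_hist <- f_hist[-1]
  }
}

#' KAIN-accelerated fixed-point iteration
#'
#' Iterates `x <- kain_step(...)` on the map `G` until the accepted
#' update norm drops below `tol`. `history = 0` gives the plain
#' (optionally damped) fixed-point iteration.
#'
#' @param G Function mapping an iterate to the next plain iterate.
#' @param x0 Starting iterate (numeric vector or array).
#' @param tol Convergence threshold on `norm_fn(x_new - x)`.
#' @param max_iter Iteration cap.
#' @param history KAIN history length (pairs retained; default 5).
#' @param damping Plain-step damping in (0, 1].
#' @param norm_fn Norm used for the convergence check (default
#'   Euclidean).
#' @return List with `x`, `iterations`, `trace` (update norms) and
#'   `converged`.
#' @export
kain_fixed_point <- function(G, x0, tol = 1e-10, max_iter = 100,
                             history = 5, damping = 1.0,
                             norm_fn = function(v) sqrt(sum(v^2))) {
  x <- x0
  x_hist <- list()
  f_hist <- list()
  trace <- numeric(0)
  for (i in seq_len(max_iter)) {
    f <- G(x) - x
    if (history > 0) {
      x_hist <- c(x_hist, list(x))
      f_hist <- c(f_hist, list(f))
      if (length(x_hist) > history) {
        x_hist <- x_hist[-1]
        f_hist <- f_hist[-1]
      }
      x_new <- kain_step(x_hist, f_hist, damping)
    } else {
      x_new <- x + damping * f
    }
    upd <- norm_fn(x_new - x)
    trace <- c(trace, upd)
    x <- x_new
    if (!all(is.finite(x))) stop("non-finite iterate in fixed-point loop")
    if (upd < tol)
      return(list(x = x, iterations = i, trace = trace, converged = TRUE))
  }
  list(x = x, iterations = max_iter, trace = trace, converged = FALSE)
}
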