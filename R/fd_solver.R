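#' Implicit finite-difference reference solution
#'
#' Numerically integrates the coupled system in boundary-fixed coordinates
#' `xi = x / L(t)`, where the growth advection cancels and the equations
#' become
#' \deqn{\partial C_i/\partial t = \frac{D}{L^2(t)}
#'   \partial^2 C_i/\partial \xi^2 - (\sigma(t) + k_i) C_i
#'   + m k_{i-1} C_{i-1},}
#' on `0 < xi < 1` with zero-flux boundaries. The scheme uses central second
#' differences with a ghost-point Neumann closure and backward Euler in
#' time, with diffusion and reaction implicit at the new time level (the
#' coupling source uses the already-updated previous generation), so it is
#' unconditionally stable; the time-dependent coefficient `D / L^2` is
#' evaluated at the new time level. The march runs in compiled code.
#'
#' A Heaviside block initial condition is discretised by cell averages: the
#' node whose cell straddles the jump at `x = gamma` receives the occupied
#' fraction of its cell, which reduces the grid sensitivity of the jump.
#'
#' @param problem An [rd_problem()].
#' @param times Output times; each must be an integer multiple of `dt`
#'   (within rounding).
#' @param dxi Spatial step on `[0, 1]`; `1/dxi` must be an integer.
#'   Default `1e-3` (1001 nodes).
#' @param dt Time step. Default `1e-3`.
#' @return A `solution_field` on the fixed xi-grid (see [solve_series()]).
#' @examples
#' prob <- rd_problem(growth_exponential(1, 0.1),
#'                    lineage_model(c(0.1, 0.2, 0.3, 0)),
#'                    D = 1e-2, ic = block_ic(1, 0.2))
#' sol <- solve_fd(prob, times = c(10, 20), dxi = 0.01, dt = 0.01)
#' @export
solve_fd <- function(problem, times, dxi = 1e-3, dt = 1e-3) {
  stopifnot(inherits(problem, "rd_problem"))
  check_time(times)
  if (dxi <= 0 || dt <= 0) stop("`dxi` and `dt` must be positive", call. = FALSE)
  if (abs(1 / dxi - round(1 / dxi)) > 1e-8)
    stop("`1/dxi` must be an integer", call. = FALSE)
  steps <- times / dt
  if (any(abs(steps - round(steps)) > 1e-6))
    stop("each output time must be a multiple of `dt`", call. = FALSE)
  steps <- as.integer(round(steps))
  if (is.unsorted(steps)) stop("`times` must be nondecreasing", call. = FALSE)

  n <- as.integer(round(1 / dxi)) + 1L
  xi <- seq(0, 1, length.out = n)
  model <- problem$lineage
  C0 <- ic_grid(problem$ic, problem$growth$L0, xi, model$G)

  nsteps <- max(steps)
  C <- if (nsteps == 0L) {
    array(C0, dim = c(n, model$G, length(steps)))
  } else {
    tnew <- dt * seq_len(nsteps)
    arr <- fd_march(C0, problem$D, dxi, dt,
                    domain_length(problem$growth, tnew)^2,
                    dilution_rate(problem$growth, tnew),
                    model$k, model$m, steps)
    array(arr, dim = c(n, model$G, length(steps)))
  }
  S <- apply(C, c(1, 3), sum)
  new_solution_field(xi = xi, x = outer(xi, domain_length(problem$growth, times)),
                     times = times, C = C, S = S, method = "fd")
}

# Nodal initial densities on the xi-grid. Block profiles are cell-averaged
# (node cells [xi_j - dxi/2, xi_j + dxi/2], half cells at the ends).
ic_grid <- function(ic, L0, xi, G) {
  n <- length(xi)
  C0 <- matrix(0, nrow = n, ncol = G)
  if (ic$kind == "block") {
    dxi <- xi[2] - xi[1]
    xg <- ic$gamma / L0
    lo <- pmax(xi - dxi / 2, 0)
    hi <- pmin(xi + dxi / 2, 1)
    frac <- pmin(pmax((xg - lo) / (hi - lo), 0), 1)
    C0[, 1] <- ic$C0 * frac
  } else {
    for (i in seq_along(ic$funs)) {
      f <- ic$funs[[i]]
      if (!is.null(f)) C0[, i] <- f(xi * L0)
    }
  }
  C0
}
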