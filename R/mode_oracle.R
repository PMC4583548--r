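#' Per-mode matrix-exponential solution
#'
#' An independent route to the exact solution that never uses the
#' uncoupling transformation and therefore places no restriction on the
#' rate pattern (distinct, repeated or mixed). In boundary-fixed
#' coordinates each cosine mode evolves independently: writing
#' \deqn{C_i(x, t) = \sum_{n=0}^{N} g_n(t) \cos(n\pi x/L(t)) b_{n,i}(t),
#'   \quad g_n(t) = e^{-(n\pi)^2 T(t)} \frac{L(0)}{L(t)},}
#' the per-mode generation-amplitude vectors satisfy the constant-coefficient
#' linear system `db_n/dt = K b_n` with `K` the [reaction_matrix()], shared
#' across modes, so `b_n(t) = expm(K t) b_n(0)` with `b_n(0)` the
#' per-generation initial Fourier coefficients. Diffusion and dilution enter
#' only through the shared scalar decay `g_n(t)`.
#'
#' The matrix exponential is computed densely (scaling and squaring via
#' \pkg{Matrix}); the generation count is small, so no structure
#' exploitation is needed.
#'
#' @inheritParams solve_series
#' @return A `solution_field` (see [solve_series()]).
#' @examples
#' prob <- rd_problem(growth_exponential(1, 0.1),
#'                    lineage_model(c(0.1, 0.1, 0.1, 0.1)),  # repeated rates
#'                    D = 1e-2, ic = block_ic(1, 0.2))
#' sol <- solve_modal(prob, times = 20, N = 200)
#' @export
solve_modal <- function(problem, times, N = 1000L, xi = NULL, x = NULL) {
  stopifnot(inherits(problem, "rd_problem"))
  check_time(times)
  if (N < 1L) stop("`N` must be at least 1", call. = FALSE)
  model <- problem$lineage
  K <- reaction_matrix(model)
  Psi0 <- ic_coefficients(problem$ic, problem$growth$L0, N, model$G)
  grid <- resolve_grid(problem, times, xi, x)
  assemble_field(problem, times, grid, N, "modal", function(t, xig) {
    E <- as.matrix(Matrix::expm(K * t))    # shared by all modes
    series_sum(problem, E %*% Psi0, xig, t)
  })
}
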