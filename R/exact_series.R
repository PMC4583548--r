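#' Exact truncated Fourier-series solution
#'
#' Evaluates the exact solution of the coupled generation densities on the
#' growing domain. The construction works in boundary-fixed coordinates
#' `xi = x / L(t)` with rescaled time `T(t)`: the uncoupled fields
#' `a_i = (W C)_i` (W the Sun-Clement [uncoupling_matrix()]) each solve a
#' single linear reaction-diffusion equation whose zero-flux solution is the
#' cosine series
#' \deqn{a_i(x, t) = \sum_{n=0}^{N} \Psi_{i,n} \cos(n\pi x / L(t))
#'   e^{-(n\pi)^2 T(t)} e^{-k_i t} \frac{L(0)}{L(t)},}
#' after which the coupled densities are recovered by the inverse transform.
#' The factor `e^{-k_i t} L(0)/L(t)` is the closed form of the combined
#' reaction-dilution decay `exp(-integral of (k_i + sigma) dt)`; for
#' exponential growth it reduces to `e^{-(alpha + k_i) t}`.
#'
#' Rate patterns are handled as follows:
#' \itemize{
#'   \item all rates pairwise distinct: uncoupling transform and inverse;
#'   \item all rates equal (generation-1-only initial condition): the
#'     L'Hopital closed form `C_i = (m k_1 t)^{i-1} / (i-1)! * C_1`;
#'   \item four generations with `k_1 = k_2 = k_3 != k_4`
#'     (generation-1-only initial condition): the printed mixed closed form;
#'   \item any other repeated pattern: delegated to the per-mode
#'     matrix-exponential solver [solve_modal()], which needs no distinctness.
#' }
#'
#' @param problem An [rd_problem()].
#' @param times Output times, `>= 0`.
#' @param N Truncation level: cosine modes `n = 0 .. N` are retained
#'   (default 1000, a conservative choice under which the examples shipped
#'   with the package are converged far below machine precision; see
#'   [choose_truncation()]).
#' @param xi Fixed relative positions in `[0, 1]` (default 101 equispaced
#'   points). Ignored when `x` is given.
#' @param x Optional fixed physical positions; must lie inside `[0, L(t)]`
#'   at every requested time.
#' @return A `solution_field` with the per-generation densities `C` (array
#'   nodes x generations x times) and the total density `S = sum_i C_i`.
#' @examples
#' prob <- rd_problem(growth_exponential(1, 0.1),
#'                    lineage_model(c(0.1, 0.2, 0.3, 0)),
#'                    D = 1e-2, ic = block_ic(1, 0.2))
#' sol <- solve_series(prob, times = c(10, 20), N = 1000)
#' sol$S[101, 2]   # total density at the moving boundary at t = 20
#' @export
solve_series <- function(problem, times, N = 1000L, xi = NULL, x = NULL) {
  stopifnot(inherits(problem, "rd_problem"))
  check_time(times)
  if (N < 1L) stop("`N` must be at least 1", call. = FALSE)
  model <- problem$lineage
  grp <- rate_pattern(model)
  g1only <- gen1_only_ic(problem$ic)

  if (max(grp) == model$G) {
    solve_series_distinct(problem, times, N, xi, x)
  } else if (max(grp) == 1L && g1only) {
    solve_series_equal(problem, times, N, xi, x)
  } else if (model$G == 4L && identical(grp, c(1L, 1L, 1L, 2L)) && g1only) {
    solve_series_mixed(problem, times, N, xi, x)
  } else {
    solve_modal(problem, times, N, xi, x)
  }
}

gen1_only_ic <- function(ic) {
  if (ic$kind == "block") return(TRUE)
  length(ic$funs) == 1L ||
    all(vapply(ic$funs[-1], is.null, logical(1)))
}

# Sum the cosine series with per-mode amplitudes B (G x (N+1)) and shared
# diffusive decay at time t, on relative positions xi; optionally applies the
# per-generation reaction decay e^{-k_i t} and always the dilution L0/L(t).
series_sum <- function(problem, B, xi, t, k = NULL) {
  N <- ncol(B) - 1L
  n <- 0:N
  decay <- exp(-(n * pi)^2 * rescaled_time(problem$growth, problem$D, t))
  cosmat <- cos(outer(n * pi, xi))              # (N+1) x npts
  A <- (B * rep(decay, each = nrow(B))) %*% cosmat
  if (!is.null(k)) A <- A * exp(-k * t)
  A * dilution_decay(problem$growth, t)
}

solve_series_distinct <- function(problem, times, N, xi, x) {
  model <- problem$lineage
  W <- uncoupling_matrix(model)
  Psi0 <- ic_coefficients(problem$ic, problem$growth$L0, N, model$G)
  PsiA <- W %*% Psi0                            # uncoupled coefficients
  grid <- resolve_grid(problem, times, xi, x)
  assemble_field(problem, times, grid, N, "series", function(t, xig) {
    A <- series_sum(problem, PsiA, xig, t, k = model$k)
    inverse_uncoupling(model, A)
  })
}

solve_series_equal <- function(problem, times, N, xi, x) {
  model <- problem$lineage
  psi1 <- ic_coefficients(problem$ic, problem$growth$L0, N, 1L)
  grid <- resolve_grid(problem, times, xi, x)
  k1 <- model$k[1]; m <- model$m; G <- model$G
  assemble_field(problem, times, grid, N, "series", function(t, xig) {
    C1 <- series_sum(problem, psi1, xig, t, k = k1)
    fac <- (m * k1 * t)^(seq_len(G) - 1L) / factorial(seq_len(G) - 1L)
    outer(fac, drop(C1))
  })
}

# Four generations, k1 = k2 = k3 != k4, generation-1-only initial condition:
# the first three generations follow the equal-rates closed form and the
# fourth combines the distinct-rate series in k4 with L'Hopital corrections.
solve_series_mixed <- function(problem, times, N, xi, x) {
  model <- problem$lineage
  psi1 <- ic_coefficients(problem$ic, problem$growth$L0, N, 1L)
  grid <- resolve_grid(problem, times, xi, x)
  k1 <- model$k[1]; k4 <- model$k[4]; m <- model$m
  r <- m * k1 / (k1 - k4)
  assemble_field(problem, times, grid, N, "series", function(t, xig) {
    base <- drop(series_sum(problem, psi1, xig, t))   # no reaction decay
    C1 <- base * exp(-k1 * t)
    C2 <- (m * k1 * t) * C1
    C3 <- (m * k1 * t)^2 / 2 * C1
    C4 <- r^3 * base * (exp(-k4 * t) - exp(-k1 * t)) -
      (m * k1 * t) * r^2 * C1 - (m * k1 * t)^2 / 2 * r * C1
    rbind(C1, C2, C3, C4, deparse.level = 0)
  })
}

# Evaluate `field_fun(t, xi_at_t)` (returning G x npts) at each time and
# pack the results into a solution_field.
assemble_field <- function(problem, times, grid, N, method, field_fun) {
  G <- problem$lineage$G
  npts <- nrow(grid$xim)
  C <- array(0, dim = c(npts, G, length(times)))
  for (j in seq_along(times)) {
    A <- field_fun(times[j], grid$xim[, j])
    C[, , j] <- t(A)
  }
  S <- apply(C, c(1, 3), sum)
  new_solution_field(xi = if (grid$fixed_x) NULL else grid$xi,
                     x = grid$xm, times = times, C = C, S = S,
                     method = method, N = N)
}

#' Evaluate one uncoupled field from its Fourier coefficients
#'
#' Evaluates `a_i(x, t)`, the i-th Sun-Clement uncoupled variable, directly
#' from a matrix of uncoupled Fourier coefficients (rows = generations,
#' columns = modes `0..N`), at physical positions `x` inside `[0, L(t)]`.
#'
#' @param problem An [rd_problem()].
#' @param Psi Matrix of uncoupled coefficients (`G` rows, `N + 1` columns).
#' @param i Generation index.
#' @param x Physical positions in `[0, L(t)]`.
#' @param t A single time, `>= 0`.
#' @return Numeric vector of `a_i(x, t)`.
#' @export
evaluate_uncoupled <- function(problem, Psi, i, x, t) {
  stopifnot(inherits(problem, "rd_problem"))
  check_time(t)
  L <- domain_length(problem$growth, t)
  if (any(x < 0 | x > L * (1 + 1e-12)))
    stop("`x` lies outside the domain [0, L(t)]", call. = FALSE)
  drop(series_sum(problem, Psi[i, , drop = FALSE], pmin(x / L, 1), t,
                  k = problem$lineage$k[i]))
}

#' Total mass of each generation by quadrature of the series solution
#'
#' Integrates the series densities over the physical domain,
#' `M_i(t) = integral of C_i(x, t) dx` on `[0, L(t)]`, by adaptive
#' quadrature in the boundary-fixed coordinate. With zero-flux boundaries,
#' diffusion and dilution conserve totals, so `M(t)` solves the pure
#' reaction system `dM/dt = K M` with `K` the [reaction_matrix()] — a useful
#' independent check of the spatial solution.
#'
#' @param problem An [rd_problem()].
#' @param t A single time.
#' @param N Truncation level.
#' @return Numeric vector of masses, one per generation.
#' @export
mass_totals <- function(problem, t, N = 200L) {
  stopifnot(inherits(problem, "rd_problem"))
  L <- domain_length(problem$growth, t)
  G <- problem$lineage$G
  vapply(seq_len(G), function(i) {
    f <- function(xiv) {
      sol <- solve_series(problem, times = t, N = N, xi = xiv)
      sol$C[, i, 1]
    }
    L * stats::integrate(f, 0, 1, rel.tol = 1e-10, abs.tol = 1e-12,
                         subdivisions = 1000L)$value
  }, numeric(1))
}

#' Truncation error of the series solution
#'
#' Computes `|S_ref(x, t) - S_N(x, t)|` for each truncation level in
#' `N_list`, where the reference is the series truncated at `N_ref` modes.
#'
#' @param problem An [rd_problem()].
#' @param N_ref Reference truncation, `> max(N_list)`.
#' @param N_list Truncation levels to compare.
#' @param x A single physical position.
#' @param t A single time.
#' @return Named numeric vector of absolute errors, one per `N_list` entry.
#' @examples
#' prob <- rd_problem(growth_exponential(1, 0.1),
#'                    lineage_model(c(0.1, 0.2, 0.3, 0)),
#'                    D = 1e-2, ic = block_ic(1, 0.2))
#' truncation_error(prob, N_ref = 1000, N_list = c(1, 2, 5, 10, 100),
#'                  x = 0, t = 20)
#' @export
truncation_error <- function(problem, N_ref, N_list, x, t) {
  stopifnot(inherits(problem, "rd_problem"))
  if (N_ref <= max(N_list))
    stop("`N_ref` must exceed every entry of `N_list`", call. = FALSE)
  S_at <- function(N) solve_series(problem, times = t, N = N, x = x)$S[1, 1]
  S_ref <- S_at(N_ref)
  err <- vapply(N_list, function(N) abs(S_ref - S_at(N)), numeric(1))
  names(err) <- paste0("N", N_list)
  err
}

#' Choose a truncation level by iterative doubling
#'
#' Evaluates the total density at `(x, t)` with successively doubled
#' truncation levels and returns the smallest level at which two successive
#' iterations agree to within `tol`.
#'
#' @param problem An [rd_problem()].
#' @param x,t Evaluation point.
#' @param tol Absolute agreement tolerance between successive iterations.
#' @param N0 Starting truncation.
#' @param N_max Safety cap.
#' @return List with `N` (the selected level) and `history`, a data frame of
#'   the levels tried and the successive differences.
#' @export
choose_truncation <- function(problem, x, t, tol = 1e-12, N0 = 1L,
                              N_max = 2^15) {
  stopifnot(inherits(problem, "rd_problem"))
  S_at <- function(N) solve_series(problem, times = t, N = N, x = x)$S[1, 1]
  N <- max(1L, as.integer(N0))
  prev <- S_at(N)
  levels <- N; diffs <- NA_real_
  repeat {
    N2 <- 2L * N
    if (N2 > N_max)
      stop("no convergence to tol = ", tol, " below N_max = ", N_max,
           call. = FALSE)
    cur <- S_at(N2)
    d <- abs(cur - prev)
    levels <- c(levels, N2); diffs <- c(diffs, d)
    if (d <= tol) {
      return(list(N = N2,
                  history = data.frame(N = levels, diff = diffs)))
    }
    N <- N2; prev <- cur
  }
}
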