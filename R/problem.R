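#' Define a coupled reaction-diffusion problem on a growing domain
#'
#' Bundles a growth law, a lineage model, a diffusivity and an initial
#' condition into the coupled system
#' \deqn{\partial C_i/\partial t = D \partial^2 C_i/\partial x^2
#'   - \partial(v C_i)/\partial x + m k_{i-1} C_{i-1} - k_i C_i}
#' on `0 < x < L(t)` with zero diffusive flux at both boundaries. Only
#' homogeneous Neumann boundaries are supported; other boundary conditions
#' raise a not-implemented error.
#'
#' @param growth A [growth_law].
#' @param lineage A [lineage_model()].
#' @param D Diffusivity (length^2/time), `> 0`.
#' @param ic An [initial_condition][block_ic()].
#' @param boundary Must be `"neumann"` (zero flux at both ends).
#' @return An object of class `rd_problem`.
#' @examples
#' prob <- rd_problem(growth_exponential(1, 0.1),
#'                    lineage_model(c(0.1, 0.2, 0.3, 0)),
#'                    D = 1e-2, ic = block_ic(1, 0.2))
#' @export
rd_problem <- function(growth, lineage, D, ic, boundary = "neumann") {
  stopifnot(inherits(growth, "growth_law"), inherits(lineage, "lineage_model"),
            inherits(ic, "initial_condition"))
  if (!is.numeric(D) || length(D) != 1L || !is.finite(D) || D <= 0)
    stop("`D` must be a single positive diffusivity", call. = FALSE)
  if (!identical(boundary, "neumann"))
    stop("only homogeneous Neumann (zero-flux) boundaries are implemented",
         call. = FALSE)
  if (ic$kind == "block" && ic$gamma > growth$L0)
    stop("`gamma` must lie in (0, L0]", call. = FALSE)
  structure(list(growth = growth, lineage = lineage, D = D, ic = ic,
                 boundary = boundary),
            class = "rd_problem")
}

#' @export
print.rd_problem <- function(x, ...) {
  cat("<rd_problem> D =", format(x$D), "| boundary: zero flux\n")
  print(x$growth)
  print(x$lineage)
  invisible(x)
}

new_solution_field <- function(xi, x, times, C, S, method, N = NULL) {
  structure(list(xi = xi, x = x, times = times, C = C, S = S,
                 method = method, N = N),
            class = "solution_field")
}

#' @export
print.solution_field <- function(x, ...) {
  cat("<solution_field>", dim(x$C)[2], "generations on",
      dim(x$C)[1], "nodes at", length(x$times), "times; method:",
      x$method, "\n")
  invisible(x)
}

#' Tidy data frame of a solution field
#'
#' @param x A `solution_field`.
#' @param row.names,optional,... Ignored (base generic signature).
#' @return Data frame with columns `t`, `x`, `xi`, `generation`, `density`,
#'   plus rows with `generation = "S"` holding the total density.
#' @export
as.data.frame.solution_field <- function(x, row.names = NULL, optional = FALSE, ...) {
  npts <- dim(x$C)[1]; G <- dim(x$C)[2]; nt <- dim(x$C)[3]
  out <- vector("list", nt)
  for (j in seq_len(nt)) {
    out[[j]] <- data.frame(
      t = x$times[j],
      x = rep(x$x[, j], G + 1L),
      xi = rep(x$xi, G + 1L),
      generation = rep(c(as.character(seq_len(G)), "S"), each = npts),
      density = c(x$C[, , j], x$S[, j]))
  }
  do.call(rbind, out)
}

# Resolve the evaluation grid: fixed-xi (default, matching scaled profiles)
# or fixed-x, which must lie inside [0, L(t)] at every requested time.
resolve_grid <- function(problem, times, xi, x) {
  L <- domain_length(problem$growth, times)
  if (!is.null(x)) {
    if (any(x < 0)) stop("`x` must be nonnegative", call. = FALSE)
    if (any(outer(x, L, `>`) & !outer(x, L, function(a, b) abs(a - b) < 1e-12 * pmax(1, b))))
      stop("`x` lies outside the domain [0, L(t)] at a requested time",
           call. = FALSE)
    xim <- pmin(outer(x, L, `/`), 1)   # npts x ntimes
    list(xi = NULL, xim = xim, xm = matrix(x, nrow = length(x), ncol = length(times)),
         L = L, fixed_x = TRUE)
  } else {
    if (is.null(xi)) xi <- seq(0, 1, length.out = 101L)
    if (any(xi < 0 | xi > 1)) stop("`xi` must lie in [0, 1]", call. = FALSE)
    list(xi = xi, xim = matrix(xi, nrow = length(xi), ncol = length(times)),
         xm = outer(xi, L), L = L, fixed_x = FALSE)
  }
}
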