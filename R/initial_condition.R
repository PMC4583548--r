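#' Initial conditions for the generation densities
#'
#' `block_ic()` is the Heaviside block profile used throughout the worked
#' examples: generation 1 at uniform density `C0` on `0 < x < gamma` and
#' zero on `gamma < x < L0`; all later generations absent at `t = 0`.
#' `general_ic()` accepts arbitrary per-generation density functions on
#' `[0, L0]`.
#'
#' @param C0 Density amplitude (cells/length), `>= 0`.
#' @param gamma Occupied width (length), must satisfy `0 < gamma <= L0` at
#'   coefficient-building time.
#' @param funs List of vectorised density functions of `x`, one per
#'   generation; use `NULL` entries (or the zero function) for initially
#'   absent generations.
#' @return An object of class `initial_condition`.
#' @examples
#' ic <- block_ic(C0 = 1, gamma = 0.2)
#' @export
block_ic <- function(C0, gamma) {
  if (!is.numeric(C0) || length(C0) != 1L || !is.finite(C0) || C0 < 0)
    stop("`C0` must be a single nonnegative density", call. = FALSE)
  if (!is.numeric(gamma) || length(gamma) != 1L || !is.finite(gamma) || gamma <= 0)
    stop("`gamma` must be a single positive width", call. = FALSE)
  structure(list(kind = "block", C0 = C0, gamma = gamma),
            class = "initial_condition")
}

#' @rdname block_ic
#' @export
general_ic <- function(funs) {
  if (!is.list(funs) || length(funs) < 1L)
    stop("`funs` must be a nonempty list of functions (or NULLs)", call. = FALSE)
  ok <- vapply(funs, function(f) is.null(f) || is.function(f), logical(1))
  if (!all(ok))
    stop("each entry of `funs` must be a function of x or NULL", call. = FALSE)
  structure(list(kind = "general", funs = funs), class = "initial_condition")
}

#' Cosine-basis Fourier coefficients of a block initial condition
#'
#' Projects the Heaviside block profile of generation 1 onto the zero-flux
#' cosine basis `cos(n pi x / L0)` on `[0, L0]`:
#' `Psi_{1,0} = C0 * gamma / L0` and
#' `Psi_{1,n} = (2 C0 / (n pi)) * sin(n pi gamma / L0)` for `n >= 1`.
#'
#' @param ic A block [block_ic()].
#' @param L0 Initial domain length.
#' @param N Truncation level: modes `n = 0 .. N` are returned.
#' @return Numeric vector of length `N + 1` (mode 0 first).
#' @export
block_ic_coefficients <- function(ic, L0, N) {
  stopifnot(inherits(ic, "initial_condition"))
  if (ic$kind != "block") stop("`ic` must be a block initial condition", call. = FALSE)
  if (N < 1L) stop("`N` must be at least 1", call. = FALSE)
  if (ic$gamma > L0)
    stop("`gamma` must lie in (0, L0]", call. = FALSE)
  n <- seq_len(N)
  c(ic$C0 * ic$gamma / L0,
    (2 * ic$C0 / (n * pi)) * sin(n * pi * ic$gamma / L0))
}

#' Cosine-basis Fourier coefficients of a general initial condition
#'
#' Computes `Psi_{i,0} = (1/L0) integral of C_i(x, 0) dx` and
#' `Psi_{i,n} = (2/L0) integral of C_i(x, 0) cos(n pi x / L0) dx` by
#' adaptive quadrature, for every generation.
#'
#' @param ic A general [general_ic()].
#' @param L0 Initial domain length.
#' @param N Truncation level.
#' @return Matrix of coefficients, `G` rows, `N + 1` columns (mode 0 first).
#' @export
general_ic_coefficients <- function(ic, L0, N) {
  stopifnot(inherits(ic, "initial_condition"))
  if (ic$kind != "general") stop("`ic` must be a general initial condition", call. = FALSE)
  if (N < 1L) stop("`N` must be at least 1", call. = FALSE)
  G <- length(ic$funs)
  Psi <- matrix(0, nrow = G, ncol = N + 1L)
  for (i in seq_len(G)) {
    f <- ic$funs[[i]]
    if (is.null(f)) next
    for (n in 0:N) {
      val <- tryCatch(
        stats::integrate(function(x) f(x) * cos(n * pi * x / L0), 0, L0,
                         rel.tol = 1e-12, abs.tol = 1e-13,
                         subdivisions = 500L)$value,
        error = function(e)
          stop("quadrature failed for generation ", i, ", mode ", n, ": ",
               conditionMessage(e), call. = FALSE))
      Psi[i, n + 1L] <- if (n == 0) val / L0 else 2 * val / L0
    }
  }
  Psi
}

#' Coefficient matrix of an initial condition
#'
#' Dispatches on the initial-condition kind and returns the full
#' per-generation coefficient matrix (block: closed form, only generation 1
#' nonzero; general: adaptive quadrature).
#'
#' @inheritParams general_ic_coefficients
#' @param G Number of generations tracked.
#' @return Matrix of coefficients, `G` rows, `N + 1` columns.
#' @export
ic_coefficients <- function(ic, L0, N, G) {
  stopifnot(inherits(ic, "initial_condition"))
  if (ic$kind == "block") {
    Psi <- matrix(0, nrow = G, ncol = N + 1L)
    Psi[1, ] <- block_ic_coefficients(ic, L0, N)
    Psi
  } else {
    Psi <- general_ic_coefficients(ic, L0, N)
    if (nrow(Psi) > G)
      stop("initial condition specifies more generations than the lineage model",
           call. = FALSE)
    rbind(Psi, matrix(0, nrow = G - nrow(Psi), ncol = N + 1L))
  }
}

#' Propagate generation-1 coefficients through the uncoupling transform
#'
#' When only generation 1 is initially occupied, the uncoupled variables
#' inherit the same spatial profile scaled by the first column of the
#' uncoupling matrix: `Psi_{i,n} = W[i, 1] * Psi_{1,n}` for every mode `n`.
#'
#' @param psi1 Coefficient vector of generation 1 (mode 0 first).
#' @param model A [lineage_model()] with distinct rates.
#' @return Matrix of uncoupled coefficients, `G` rows, `length(psi1)` columns.
#' @export
propagate_coefficients <- function(psi1, model) {
  stopifnot(inherits(model, "lineage_model"))
  W <- uncoupling_matrix(model)
  outer(W[, 1], psi1)
}
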