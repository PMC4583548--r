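#' Cell lineage model: a chain of generations with first-order rates
#'
#' Generation `i` is converted into generation `i + 1` at rate `k[i]`,
#' producing `m` cells per parent: `m = 2` models proliferation (each cell
#' divides into two daughters of the next generation), `m = 1` models
#' differentiation (each cell changes type without dividing). The reaction
#' terms are linear, so the density of generation `i` obeys
#' `dC_i/dt = m * k[i-1] * C_{i-1} - k[i] * C_i` in a well-mixed setting.
#'
#' @param k Numeric vector of per-generation rates `k_1 .. k_G` (1/time).
#'   Negative rates are accepted with a warning (the uncoupled equations can
#'   then be unbounded).
#' @param m Amplification factor: 2 (proliferation, default) or 1
#'   (differentiation). Other positive values are accepted with a warning,
#'   as the linear algebra does not require integrality.
#' @return An object of class `lineage_model` with fields `k`, `m`, `G`.
#' @examples
#' lin <- lineage_model(k = c(0.1, 0.2, 0.3, 0), m = 2)
#' reaction_matrix(lin)
#' uncoupling_matrix(lin)
#' @export
lineage_model <- function(k, m = 2) {
  if (!is.numeric(k) || length(k) < 1L || any(!is.finite(k)))
    stop("`k` must be a nonempty finite numeric vector", call. = FALSE)
  if (!is.numeric(m) || length(m) != 1L || !is.finite(m) || m <= 0)
    stop("`m` must be a single positive number", call. = FALSE)
  if (!m %in% c(1, 2))
    warning("amplification factor m = ", m,
            " is neither 1 (differentiation) nor 2 (proliferation)")
  if (any(k < 0))
    warning("negative rates k can make the uncoupled solutions unbounded")
  structure(list(k = as.numeric(k), m = m, G = length(k)),
            class = "lineage_model")
}

#' @export
print.lineage_model <- function(x, ...) {
  cat("<lineage_model> G =", x$G, "generations, m =", x$m,
      "\n  k =", paste(format(x$k), collapse = ", "), "\n")
  invisible(x)
}

# Two rates are "equal" for the uncoupling transform when they agree to
# within this relative tolerance; below it the transform is singular.
rates_equal <- function(ki, kj) {
  abs(ki - kj) <= 1e-8 * max(1, abs(ki), abs(kj))
}

#' Partition generations into groups of (numerically) equal rates
#'
#' Rates within relative tolerance `1e-8` of an earlier rate join its group.
#' The uncoupling transformation requires all groups to be singletons.
#'
#' @param model A [lineage_model()].
#' @return Integer vector of group labels, one per generation.
#' @export
rate_pattern <- function(model) {
  stopifnot(inherits(model, "lineage_model"))
  grp <- integer(model$G)
  ngrp <- 0L
  for (i in seq_len(model$G)) {
    hit <- 0L
    for (j in seq_len(i - 1L)) {
      if (rates_equal(model$k[i], model$k[j])) { hit <- grp[j]; break }
    }
    if (hit == 0L) { ngrp <- ngrp + 1L; hit <- ngrp }
    grp[i] <- hit
  }
  grp
}

has_distinct_rates <- function(model) {
  max(rate_pattern(model)) == model$G
}

stop_repeated_rates <- function(model) {
  grp <- rate_pattern(model)
  dup <- which(duplicated(grp))[1]
  first <- which(grp == grp[dup])[1]
  stop(sprintf(paste0("uncoupling transformation requires distinct rates: ",
                      "k[%d] = %g and k[%d] = %g coincide (within tolerance); ",
                      "use the modal solver or the repeated-rate closed forms"),
               first, model$k[first], dup, model$k[dup]), call. = FALSE)
}

#' Reaction matrix of the lineage chain
#'
#' Returns the lower-bidiagonal matrix `K` with `K[i, i] = -k[i]` and
#' `K[i, i-1] = m * k[i-1]`, so that the well-mixed densities satisfy
#' `dC/dt = K C`.
#'
#' @param model A [lineage_model()].
#' @return A `G x G` numeric matrix.
#' @export
reaction_matrix <- function(model) {
  stopifnot(inherits(model, "lineage_model"))
  G <- model$G
  K <- diag(-model$k, nrow = G)
  if (G > 1L)
    K[cbind(2:G, 1:(G - 1L))] <- model$m * model$k[1:(G - 1L)]
  K
}

#' Sun-Clement uncoupling matrix
#'
#' The unit lower-triangular matrix `W` with
#' `W[i, j] = prod_{l = j}^{i-1} m k_l / (k_l - k_i)` for `j < i`, such that
#' `a = W C` diagonalises the reaction chain:
#' `W K W^{-1} = diag(-k)`. Each transformed variable `a_i` then satisfies an
#' uncoupled linear reaction-diffusion equation with rate `k_i`. Requires all
#' rates pairwise distinct (see [rate_pattern()]).
#'
#' @param model A [lineage_model()].
#' @return A `G x G` unit lower-triangular matrix.
#' @export
uncoupling_matrix <- function(model) {
  stopifnot(inherits(model, "lineage_model"))
  if (!has_distinct_rates(model)) stop_repeated_rates(model)
  G <- model$G
  k <- model$k
  W <- diag(1, G)
  for (i in seq_len(G)) {
    for (j in seq_len(i - 1L)) {
      l <- j:(i - 1L)
      W[i, j] <- prod(model$m * k[l] / (k[l] - k[i]))
    }
  }
  W
}

#' Invert the uncoupling transformation
#'
#' Given the uncoupled fields `a = W C`, recovers the generation densities
#' `C` by forward substitution (W is unit lower triangular).
#'
#' @param model A [lineage_model()].
#' @param a Numeric vector of length `G`, or a matrix with `G` rows (one
#'   column per evaluation point).
#' @return Same shape as `a`.
#' @export
inverse_uncoupling <- function(model, a) {
  stopifnot(inherits(model, "lineage_model"))
  W <- uncoupling_matrix(model)
  vec <- is.null(dim(a))
  a <- if (vec) matrix(a, ncol = 1) else as.matrix(a)
  if (nrow(a) != model$G)
    stop("`a` must have one row per generation", call. = FALSE)
  C <- a
  for (i in seq_len(model$G)) {
    for (j in seq_len(i - 1L)) C[i, ] <- C[i, ] - W[i, j] * C[j, ]
  }
  if (vec) drop(C) else C
}
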