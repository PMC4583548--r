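#' Uniform domain-growth laws
#'
#' A growth law describes a uniformly growing one-dimensional domain
#' `0 < x < L(t)`: the length `L(t)`, the dilution rate
#' `sigma(t) = L'(t)/L(t)` (the local stretch rate, independent of position
#' under uniform growth), the induced advection velocity
#' `v(x, t) = x * sigma(t)` (origin fixed, elongation in the positive
#' x-direction), and the rescaled time `T(t) = integral of D / L(s)^2 ds`
#' that renders the diffusion coefficient constant in the boundary-fixed
#' frame.
#'
#' Three kinds are supported:
#' \describe{
#'   \item{exponential}{`L(t) = L0 * exp(alpha * t)`, so `sigma(t) = alpha`
#'     and `v(x, t) = alpha * x`.}
#'   \item{linear}{`L(t) = L0 + beta * t`, so
#'     `sigma(t) = beta / (L0 + beta * t)`.}
#'   \item{custom}{an arbitrary user-supplied length function `L(t)`;
#'     `sigma` is obtained by finite-difference differentiation of
#'     `log(L)` and `T(t)` by adaptive quadrature.}
#' }
#'
#' Shrinking domains (`dL/dt < 0`) are not supported: only growing (or
#' static, `beta = 0` / `alpha = 0`) domains are modelled.
#'
#' @param L0 Initial domain length, `> 0`.
#' @param alpha Exponential growth rate (1/time), `>= 0`.
#' @param beta Linear elongation rate (length/time), `>= 0`.
#' @param length_fun For [growth_custom()], a vectorised function of time
#'   returning `L(t) > 0`, nondecreasing on the range of interest.
#' @return An object of class `growth_law`.
#' @examples
#' g <- growth_exponential(L0 = 1, alpha = 0.1)
#' domain_length(g, 20)            # e^2 ~= 7.389
#' dilution_rate(g, 5)             # constant alpha = 0.1
#' rescaled_time(g, D = 1e-2, 20)  # D (1 - exp(-2 alpha t)) / (2 alpha L0^2)
#' @name growth_law
NULL

new_growth_law <- function(kind, L0, pars) {
  structure(c(list(kind = kind, L0 = L0), pars), class = "growth_law")
}

#' @rdname growth_law
#' @export
growth_exponential <- function(L0, alpha) {
  if (!is.numeric(L0) || length(L0) != 1L || !is.finite(L0) || L0 <= 0)
    stop("`L0` must be a single positive number", call. = FALSE)
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha))
    stop("`alpha` must be a single finite number", call. = FALSE)
  if (alpha < 0)
    stop("shrinking domains (alpha < 0) are not supported", call. = FALSE)
  new_growth_law("exponential", L0, list(alpha = alpha))
}

#' @rdname growth_law
#' @export
growth_linear <- function(L0, beta) {
  if (!is.numeric(L0) || length(L0) != 1L || !is.finite(L0) || L0 <= 0)
    stop("`L0` must be a single positive number", call. = FALSE)
  if (!is.numeric(beta) || length(beta) != 1L || !is.finite(beta))
    stop("`beta` must be a single finite number", call. = FALSE)
  if (beta < 0)
    stop("shrinking domains (beta < 0) are not supported", call. = FALSE)
  new_growth_law("linear", L0, list(beta = beta))
}

#' @rdname growth_law
#' @export
growth_custom <- function(length_fun) {
  if (!is.function(length_fun))
    stop("`length_fun` must be a function of time", call. = FALSE)
  L0 <- length_fun(0)
  if (!is.finite(L0) || L0 <= 0)
    stop("`length_fun(0)` must be a positive length", call. = FALSE)
  new_growth_law("custom", L0, list(length_fun = length_fun))
}

#' @export
print.growth_law <- function(x, ...) {
  cat("<growth_law:", x$kind, "> L0 =", format(x$L0))
  if (x$kind == "exponential") cat(", alpha =", format(x$alpha))
  if (x$kind == "linear") cat(", beta =", format(x$beta))
  cat("\n")
  invisible(x)
}

check_time <- function(t) {
  if (!is.numeric(t) || any(!is.finite(t)) || any(t < 0))
    stop("`t` must be finite and nonnegative", call. = FALSE)
  t
}

#' @rdname growth_law
#' @param law A `growth_law`.
#' @param t Time(s), `>= 0` (vectorised).
#' @export
domain_length <- function(law, t) {
  stopifnot(inherits(law, "growth_law"))
  check_time(t)
  switch(law$kind,
    exponential = law$L0 * exp(law$alpha * t),
    linear      = law$L0 + law$beta * t,
    custom      = {
      L <- vapply(t, law$length_fun, numeric(1))
      if (any(!is.finite(L) | L <= 0))
        stop("custom length function returned a nonpositive length", call. = FALSE)
      L
    })
}

#' @rdname growth_law
#' @export
dilution_rate <- function(law, t) {
  stopifnot(inherits(law, "growth_law"))
  check_time(t)
  switch(law$kind,
    exponential = rep_len(law$alpha, length(t)),
    linear      = law$beta / (law$L0 + law$beta * t),
    custom      = vapply(t, function(ti) {
      # sigma = d log L / dt by central differences; L(t) is the primitive
      h <- 1e-6 * max(1, ti)
      lo <- max(ti - h, 0)
      (log(law$length_fun(ti + h)) - log(law$length_fun(lo))) / (ti + h - lo)
    }, numeric(1)))
}

#' @rdname growth_law
#' @param x Position(s) within `[0, L(t)]`.
#' @export
growth_velocity <- function(law, x, t) {
  x * dilution_rate(law, t)
}

#' @rdname growth_law
#' @param D Diffusivity (length^2/time), `> 0`.
#' @export
rescaled_time <- function(law, D, t) {
  stopifnot(inherits(law, "growth_law"))
  check_time(t)
  if (!is.numeric(D) || length(D) != 1L || !is.finite(D) || D <= 0)
    stop("`D` must be a single positive diffusivity", call. = FALSE)
  switch(law$kind,
    exponential = {
      a <- law$alpha
      if (a == 0) D * t / law$L0^2
      else D * (1 - exp(-2 * a * t)) / (2 * a * law$L0^2)
    },
    linear = {
      b <- law$beta
      if (b == 0) D * t / law$L0^2
      else (D / b) * (1 / law$L0 - 1 / (law$L0 + b * t))
    },
    custom = vapply(t, function(ti) {
      if (ti == 0) return(0)
      stats::integrate(function(s) D / domain_length(law, s)^2,
                       0, ti, abs.tol = 1e-12, rel.tol = 1e-12)$value
    }, numeric(1)))
}

#' @rdname growth_law
#' @details `dilution_decay(law, t)` returns `L(0)/L(t)`, the accumulated
#'   dilution factor `exp(-integral of sigma ds)`; for exponential growth it
#'   equals `exp(-alpha * t)`.
#' @export
dilution_decay <- function(law, t) {
  law$L0 / domain_length(law, t)
}
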