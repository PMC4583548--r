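test_that("nongrowing single-species heat limit matches an independent cosine series", {
  # static domain, one generation, no reaction: the classical heat equation
  prob <- rd_problem(growth_linear(L0 = 1, beta = 0), lineage_model(0),
                     D = 0.05, ic = block_ic(C0 = 1, gamma = 0.3))
  xi <- seq(0, 1, length.out = 51)
  sol <- solve_series(prob, times = 2, N = 400, xi = xi)
  # independently coded heat-kernel cosine series
  ref <- rep(0.3, length(xi))
  for (n in 1:400) {
    ref <- ref + (2 / (n * pi)) * sin(n * pi * 0.3) *
      cos(n * pi * xi) * exp(-(n * pi)^2 * 0.05 * 2)
  }
  expect_lt(max(abs(sol$C[, 1, 1] - ref)), 1e-10)
})

test_that("series reconstructs the initial condition away from the jump", {
  prob <- example_problem(D = 1e-2)
  xi <- seq(0, 1, length.out = 501)
  sol <- solve_series(prob, times = 0, N = 8000, xi = xi)
  target <- ifelse(xi < 0.2, 1, 0)
  keep <- abs(xi - 0.2) > 0.02   # exclude the Gibbs window around the jump
  expect_lt(max(abs(sol$C[keep, 1, 1] - target[keep])), 1e-3)
  expect_lt(max(abs(sol$C[, 2:4, 1])), 1e-12)
})

test_that("uniform initial condition leaves only the constant mode", {
  prob <- rd_problem(growth_exponential(1, 0.1), lineage_model(0.25),
                     D = 1e-2, ic = block_ic(C0 = 2, gamma = 1))
  Psi <- ic_coefficients(prob$ic, 1, N = 50, G = 1)
  x <- c(0, 0.7, 1.5)
  a <- evaluate_uncoupled(prob, Psi, i = 1, x = x, t = 6)
  expect_equal(a, rep(2 * exp(-6 * (0.1 + 0.25)), 3), tolerance = 1e-12)
})

test_that("series satisfies zero flux at both moving boundaries", {
  prob <- example_problem(D = 1e-2)
  t <- 10
  L <- domain_length(prob$growth, t)
  h <- 1e-6
  for (edge in c(0, 1)) {
    xi_pts <- if (edge == 0) c(0, h, 2 * h) else c(1 - 2 * h, 1 - h, 1)
    sol <- solve_series(prob, times = t, N = 500, xi = xi_pts)
    # one-sided second-order derivative estimate of S at the edge
    S <- if (edge == 0) sol$S[, 1] else rev(sol$S[, 1])
    dS <- (-3 * S[1] + 4 * S[2] - S[3]) / (2 * h * L)
    expect_lt(abs(dS), 1e-6 * max(abs(S)))
  }
})

test_that("out-of-domain and invalid-boundary requests error", {
  prob <- example_problem()
  Psi <- ic_coefficients(prob$ic, 1, N = 10, G = 4)
  expect_error(evaluate_uncoupled(prob, Psi, 1, x = 2, t = 0), "outside")
  expect_error(solve_series(prob, times = 5, x = 10), "outside")
  expect_error(rd_problem(prob$growth, prob$lineage, 1e-2, prob$ic,
                          boundary = "dirichlet"), "Neumann")
})

test_that("fixed-x and fixed-xi evaluation agree on shared points", {
  prob <- example_problem(D = 1e-2)
  times <- c(5, 12)
  L <- domain_length(prob$growth, times)
  sol_xi <- solve_series(prob, times = times, N = 300, xi = 0.5)
  sol_x <- lapply(seq_along(times), function(j)
    solve_series(prob, times = times[j], N = 300, x = 0.5 * L[j]))
  for (j in seq_along(times))
    expect_equal(sol_xi$C[1, , j], sol_x[[j]]$C[1, , 1], tolerance = 1e-12)
})

test_that("equal-rates closed form carries the factorial cascade", {
  prob <- example_problem(k = rep(0.1, 4))
  xi <- seq(0, 1, length.out = 41)
  sol <- solve_series(prob, times = c(10, 20), N = 500, xi = xi)
  for (j in 1:2) {
    t <- sol$times[j]
    C1 <- sol$C[, 1, j]
    keep <- C1 > 1e-12
    expect_equal(sol$C[keep, 2, j] / C1[keep], rep(2 * 0.1 * t, sum(keep)),
                 tolerance = 1e-12)
    expect_equal(sol$C[keep, 3, j] / C1[keep],
                 rep((2 * 0.1 * t)^2 / 2, sum(keep)), tolerance = 1e-12)
    expect_equal(sol$C[keep, 4, j] / C1[keep],
                 rep((2 * 0.1 * t)^3 / 6, sum(keep)), tolerance = 1e-12)
  }
})

test_that("mixed repeated/distinct closed form agrees with the modal solver", {
  prob <- example_problem(k = c(0.1, 0.1, 0.1, 0))
  xi <- seq(0, 1, length.out = 101)
  ser <- solve_series(prob, times = c(10, 20), N = 400, xi = xi)
  expect_identical(ser$method, "series")
  mod <- solve_modal(prob, times = c(10, 20), N = 400, xi = xi)
  expect_lt(max(abs(ser$C - mod$C)), 1e-12)
})

test_that("other repeated patterns are delegated to the modal solver", {
  prob <- example_problem(k = c(0.1, 0.2, 0.2, 0))
  sol <- solve_series(prob, times = 5, N = 100, xi = c(0, 0.5, 1))
  expect_identical(sol$method, "modal")
  expect_true(all(is.finite(sol$S)))
})

test_that("general decay factor is exact on linearly growing domains", {
  # the reaction-dilution factor exp(-k t) L0/L(t) is asserted against the
  # finite-difference solution for linear growth, where no closed
  # exponential-growth shortcut applies
  prob <- rd_problem(growth_linear(1, 0.25), lineage_model(c(0.12, 0.3)),
                     D = 5e-3, ic = block_ic(1, 0.4))
  fd <- solve_fd(prob, times = 4, dxi = 2e-3, dt = 2e-4)
  ser <- solve_series(prob, times = 4, N = 600, xi = fd$xi)
  expect_lt(max(abs(fd$S - ser$S)), 5e-3 * max(ser$S))
})

test_that("distinct-rate evaluation converges to the equal-rates limit", {
  # two generations, k2 = k1 + eps: the indeterminate rate-ratio form tends
  # to the L'Hopital closed form as eps shrinks
  xi <- seq(0, 1, length.out = 81)
  equal <- solve_series(example_problem(k = c(0.1, 0.1)), times = 20,
                        N = 300, xi = xi)
  errs <- vapply(c(1e-2, 1e-3, 1e-4), function(eps) {
    pert <- solve_series(example_problem(k = c(0.1, 0.1 + eps)), times = 20,
                         N = 300, xi = xi)
    max(abs(pert$C[, 2, 1] - equal$C[, 2, 1]))
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
  # first-order Richardson extrapolation of the eps-linear error to eps = 0
  extrap <- errs[3] - (errs[2] - errs[3]) / 9
  expect_lt(abs(extrap), 1e-6)
})

test_that("mass totals follow the pure reaction kinetics", {
  prob <- example_problem(D = 1e-2)
  M <- mass_totals(prob, t = 6, N = 200)
  expect_equal(M[1], 0.2 * exp(-0.1 * 6), tolerance = 1e-9)
  K <- reaction_matrix(prob$lineage)
  Mref <- as.numeric(Matrix::expm(K * 6) %*% c(0.2, 0, 0, 0))
  expect_equal(M, Mref, tolerance = 1e-8)
})

test_that("truncation error decreases and the doubling rule picks a small N", {
  prob <- example_problem(D = 1e-2)
  err <- truncation_error(prob, N_ref = 1000, N_list = c(1, 2, 5, 10, 100),
                          x = 0, t = 20)
  expect_true(all(diff(err) <= 0))
  expect_lt(err[["N10"]], 1e-13)
  expect_error(truncation_error(prob, N_ref = 50, N_list = c(10, 100)),
               "exceed")
  pick <- choose_truncation(prob, x = 0, t = 20, tol = 1e-12)
  expect_lte(pick$N, 64)
  expect_lte(utils::tail(pick$history$diff, 1), 1e-12)
})
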