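test_that("exponential growth law gives the stated length, dilution and velocity", {
  g <- growth_exponential(L0 = 1, alpha = 0.1)
  expect_equal(domain_length(g, 20), exp(2), tolerance = 1e-12)
  expect_equal(domain_length(g, 0), 1)
  expect_equal(dilution_rate(g, c(0, 5, 30)), rep(0.1, 3))
  expect_equal(growth_velocity(g, 0, 5), 0)
  expect_equal(growth_velocity(g, 2, 5), 0.2)
})

test_that("linear growth law covers elongating and static domains", {
  g <- growth_linear(L0 = 1, beta = 0.5)
  expect_equal(domain_length(g, 2), 2)
  expect_equal(dilution_rate(g, 0), 0.5)
  g0 <- growth_linear(L0 = 2, beta = 0)
  expect_equal(domain_length(g0, c(0, 7, 100)), rep(2, 3))
  expect_equal(dilution_rate(g0, c(1, 10)), c(0, 0))
  expect_equal(dilution_decay(g0, 50), 1)
})

test_that("invalid growth parameters are rejected", {
  expect_error(growth_exponential(0, 0.1), "positive")
  expect_error(growth_exponential(-1, 0.1), "positive")
  expect_error(growth_linear(1, -0.2), "shrinking")
  expect_error(growth_exponential(1, -0.1), "shrinking")
  expect_error(domain_length(growth_linear(1, 1), -2), "nonnegative")
  expect_error(rescaled_time(growth_linear(1, 1), D = -1, 2), "positive")
})

test_that("rescaled time matches its closed forms and the quadrature oracle", {
  # worked values
  ge <- growth_exponential(1, 0.1)
  expect_equal(rescaled_time(ge, D = 1e-2, 20), 0.05 * (1 - exp(-4)),
               tolerance = 1e-12)
  gl <- growth_linear(1, 1)
  expect_equal(rescaled_time(gl, D = 1, 1), 0.5, tolerance = 1e-12)
  expect_equal(rescaled_time(ge, D = 1, 0), 0)

  set.seed(41)
  for (rep in 1:20) {
    t <- stats::runif(1, 0, 50)
    law <- switch(sample(3, 1),
                  growth_exponential(stats::runif(1, 0.5, 2), stats::runif(1, 0, 0.2)),
                  growth_linear(stats::runif(1, 0.5, 2), stats::runif(1, 0, 0.5)),
                  growth_custom(function(s) 1 + 0.3 * s + 0.05 * s^2))
    D <- 10^stats::runif(1, -3, 0)
    expect_equal(rescaled_time(law, D, t), quadrature_rescaled_time(law, D, t),
                 tolerance = 1e-10)
  }
})

test_that("dilution rate equals the log-derivative of length for every law kind", {
  set.seed(42)
  laws <- list(growth_exponential(1.3, 0.12),
               growth_linear(0.8, 0.4),
               growth_custom(function(t) 2 * sqrt(1 + t)))
  for (law in laws) {
    for (t in stats::runif(20, 0.1, 50)) {
      h <- 1e-5 * max(1, t)
      num <- (log(domain_length(law, t + h)) - log(domain_length(law, t - h))) / (2 * h)
      expect_equal(dilution_rate(law, t), num, tolerance = 1e-5)
    }
  }
})

test_that("velocity is proportional to position (uniform growth)", {
  set.seed(43)
  law <- growth_custom(function(t) 1 + t + 0.1 * t^2)
  for (t in stats::runif(5, 0, 20)) {
    x <- stats::runif(6, 0.01, 5)
    ratio <- growth_velocity(law, x, t) / x
    expect_lt(diff(range(ratio)), 1e-12 * max(1, abs(ratio[1])))
  }
})

test_that("dilution decay is the inverse relative elongation", {
  g <- growth_exponential(1, 0.1)
  expect_equal(dilution_decay(g, 20), exp(-2), tolerance = 1e-12)
  expect_equal(dilution_decay(g, 0), 1)
  gl <- growth_linear(2, 0.5)
  expect_equal(dilution_decay(gl, 4), 2 / 4)
})
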