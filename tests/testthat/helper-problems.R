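# Shared fixtures: the worked four-generation example problems and a
# random-problem generator for property-style tests.

# Four generations on an exponentially growing domain, block initial
# condition of width 0.2; D and the rate vector distinguish the variants.
example_problem <- function(D = 1e-2, k = c(0.1, 0.2, 0.3, 0), m = 2,
                            alpha = 0.1, L0 = 1, C0 = 1, gamma = 0.2) {
  rd_problem(growth_exponential(L0, alpha), lineage_model(k, m = m),
             D = D, ic = block_ic(C0, gamma))
}

# Random problem draw. Rates are drawn distinct unless `pattern` forces
# duplicates ("repeated" copies one rate into a later slot).
random_problem <- function(G = sample(2:6, 1), pattern = c("distinct", "repeated"),
                           growth = c("exponential", "linear"),
                           D = 10^stats::runif(1, -2.3, -1.3)) {
  pattern <- match.arg(pattern)
  growth <- match.arg(growth)
  k <- round(stats::runif(G, 0.05, 0.5), 3)
  while (anyDuplicated(k)) k <- round(stats::runif(G, 0.05, 0.5), 3)
  if (pattern == "repeated" && G >= 2) {
    j <- sample(seq_len(G - 1), 1)
    k[j + 1] <- k[j]
  }
  law <- if (growth == "exponential") {
    growth_exponential(L0 = 1, alpha = stats::runif(1, 0, 0.15))
  } else {
    growth_linear(L0 = 1, beta = stats::runif(1, 0, 0.3))
  }
  rd_problem(law, lineage_model(k, m = sample(1:2, 1)),
             D = D, ic = block_ic(C0 = stats::runif(1, 0.5, 2),
                                  gamma = stats::runif(1, 0.1, 0.9)))
}

has_distinct_rates_test <- function(model) {
  max(rate_pattern(model)) == model$G
}

# Independent quadrature oracle for the rescaled time T(t).
quadrature_rescaled_time <- function(law, D, t) {
  if (t == 0) return(0)
  stats::integrate(function(s) D / domain_length(law, s)^2, 0, t,
                   rel.tol = 1e-13, abs.tol = 1e-15)$value
}
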