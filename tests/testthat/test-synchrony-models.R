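test_that("beta-binomial count pmf is a proper law with the right edge cases", {
  for (K in c(2, 5, 50, 1000)) {
    for (rho in c(0.01, 0.03, 0.25, 0.9)) {
      pmf <- betabinomial_count_pmf(K, rho = rho)
      expect_length(pmf, K)
      expect_true(all(pmf >= 0))
      expect_equal(sum(pmf), 1, tolerance = 1e-12)
    }
  }
  expect_equal(betabinomial_count_pmf(1, beta = 3), 1)
  ## asynchronous limit: no coactivation
  expect_equal(betabinomial_count_pmf(2, beta = Inf), c(1, 0))
  expect_error(betabinomial_count_pmf(0, beta = 1), "empty ensemble")
  expect_error(betabinomial_count_pmf(3, beta = -1), "beta")
})

test_that("the pmf induces the requested pairwise correlation", {
  ## enumeration of the count law, pairwise coefficient via factorial moments
  for (rho in c(0.03, 0.1, 0.4)) {
    for (K in c(2, 5, 20)) {
      pmf <- betabinomial_count_pmf(K, rho = rho)
      expect_equal(pool_corr_oracle(pmf, K, 2), rho, tolerance = 1e-10)
    }
  }
  ## K=5, beta = 32.333 corresponds to rho = 0.03
  pmf <- betabinomial_count_pmf(5, beta = 32.333333333333336)
  expect_equal(pool_corr_oracle(pmf, 5, 2), 0.03, tolerance = 1e-12)
})

test_that("order-n correlations follow the product formula", {
  for (rho in c(0.05, 0.2, 0.5)) {
    beta <- 1 / rho - 1
    for (K in c(4, 6, 8)) {
      pmf <- betabinomial_count_pmf(K, rho = rho)
      for (n in 2:4) {
        expect_equal(pool_corr_oracle(pmf, K, n),
                     prod(seq_len(n - 1) / (beta + seq_len(n - 1))),
                     tolerance = 1e-10)
        expect_equal(betabinomial_correlation(rho, n),
                     pool_corr_oracle(pmf, K, n), tolerance = 1e-10)
      }
    }
  }
  ## third order equals 2 rho^2 / (1 + rho)
  expect_equal(betabinomial_correlation(0.03, 3), 2 * 0.03^2 / 1.03,
               tolerance = 1e-12)
})

test_that("collective event rate matches the brute-force K/E[count] oracle", {
  for (K in c(2, 10, 1000, 10000)) {
    for (rho in c(0.01, 0.03, 0.3)) {
      pmf <- betabinomial_count_pmf(K, rho = rho)
      expect_equal(betabinomial_event_rate(K, 1.7, rho),
                   pool_rate_oracle(K, 1.7, pmf),
                   tolerance = 1e-10)
    }
  }
  ## K = 2 closed form r (2 beta + 1) / (1 + beta)
  beta <- 1 / 0.2 - 1
  expect_equal(betabinomial_event_rate(2, 3, 0.2),
               3 * (2 * beta + 1) / (1 + beta), tolerance = 1e-12)
})

test_that("event rates: additivity without synchrony, marginals always", {
  m <- mixture_model(independent_pool(10, 2, "e", 0.01),
                     independent_pool(4, 5, "i", 0.04))
  expect_equal(event_rate(m), 10 * 2 + 4 * 5)
  ## a singleton input subset recovers its own rate
  expect_equal(event_rate(m, inputs = 1), 2)
  expect_equal(event_rate(m, inputs = 11), 5)
  ## b * E[X_k] = r_k also under synchrony
  bb <- betabinomial_pool(100, 1.3, 0.05)
  expect_equal(event_rate(bb, inputs = 7), 1.3, tolerance = 1e-10)
  expect_error(event_rate(m, neurons = integer(0)), "empty")
})

test_that("subsampling monotonicity holds on randomized small ensembles", {
  set.seed(42)
  for (rep in 1:5) {
    parts <- lapply(1:3, function(i) {
      betabinomial_pool(sample(2:6, 1), runif(1, 1, 10), runif(1, 0, 0.9),
                        sample(c("e", "i"), 1), weight = 0.01,
                        neurons = sample(1:3, sample(1:3, 1)), n_neurons = 3)
    })
    m <- mixture_model(parts, n_neurons = 3)
    for (a in 1:3) {
      others <- setdiff(1:3, a)
      expect_lte(event_rate(m, neurons = a),
                 event_rate(m, neurons = c(a, others[1])) + 1e-12)
      expect_lte(event_rate(m, neurons = c(a, others[1])),
                 event_rate(m, neurons = 1:3) + 1e-12)
    }
    ## input-level monotonicity
    ids <- m$input_table$id
    s1 <- sample(ids, 2); s2 <- union(s1, sample(ids, 3))
    expect_lte(event_rate(m, inputs = s1), event_rate(m, inputs = s2) + 1e-12)
  }
})

test_that("spiking correlation: extremes and exact enumeration agree", {
  expect_equal(spiking_correlation(synchronous_pool(5, 2), c(1, 4)), 1)
  expect_equal(spiking_correlation(independent_pool(5, 2), c(1, 4)), 0)
  expect_equal(spiking_correlation(independent_pool(5, 2), 3), 1)  # order 1
  bb <- betabinomial_pool(6, 2, 0.2)
  pp <- pattern_pmf(bb)
  expect_equal(spiking_correlation(bb, c(2, 5)),
               pattern_corr_oracle(pp$patterns, pp$prob, c(2, 5)),
               tolerance = 1e-10)
  expect_equal(spiking_correlation(bb, c(1, 3, 6)),
               pattern_corr_oracle(pp$patterns, pp$prob, c(1, 3, 6)),
               tolerance = 1e-10)
  expect_error(spiking_correlation(bb, 99), "unknown")
  zero <- independent_pool(2, 0, "e", 0.01)
  expect_error(spiking_correlation(zero, 1:2), "zero marginal")
})

test_that("pattern enumeration excludes the silent pattern and sums to one", {
  pp <- pattern_pmf(betabinomial_pool(3, 5, 0.2))
  expect_equal(nrow(pp$patterns), 7)      # 2^3 - 1 nonzero patterns
  expect_equal(sum(pp$prob), 1, tolerance = 1e-12)
  expect_true(all(rowSums(pp$patterns) >= 1))
})

test_that("pair event rate covers the independent, shared and mixed regimes", {
  ## independent inputs to the two neurons: q12 = 0, b12 = b1 + b2
  ind <- mixture_model(independent_pool(5, 2, "e", 0.01, neurons = 1,
                                        n_neurons = 2),
                       independent_pool(5, 2, "e", 0.01, neurons = 2,
                                        n_neurons = 2))
  pe <- pair_event_rate(ind)
  expect_equal(pe$q12, 0, tolerance = 1e-12)
  expect_equal(pe$b12, pe$b1 + pe$b2, tolerance = 1e-10)
  ## optimally synchronous: one shared pool, b12 = max(b1, b2)
  sh <- betabinomial_pool(10, 2, 0.1, neurons = 1:2)
  ps <- pair_event_rate(sh)
  expect_equal(ps$b12, max(ps$b1, ps$b2), tolerance = 1e-10)
  expect_equal(ps$q12, min(ps$b1, ps$b2) / max(ps$b1, ps$b2), tolerance = 1e-10)
  ## calibrated synchrony: strict inequalities
  m <- calibrate_mixture(list(rho_e = 0.04, rho_i = 0.04, rho_cross_ee = 0.02,
                              rho_cross_ii = 0.02),
                         Ke = 10, Ki = 4, re = 5, ri = 5,
                         we = 0.01, wi = 0.04)
  pm <- pair_event_rate(m)
  expect_gt(pm$b12, max(pm$b1, pm$b2))
  expect_lt(pm$b12, pm$b1 + pm$b2)
})
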