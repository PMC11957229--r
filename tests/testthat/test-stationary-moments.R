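p <- neuron_params()

test_that("no input means rest voltage and vanishing moments", {
  z <- independent_pool(5, 0, "e", 0.01)
  expect_equal(stationary_mean(z, p)$mean[[1]], p$rest)
  expect_equal(stationary_moment(z, p, c(1, 1))$central, 0)
  expect_equal(stationary_moment(z, p, c(1, 1, 1))$shifted, 0)
})

test_that("the stationary mean matches its direct exponential-efficacy form", {
  ## asynchronous drive: m = sum r (1 - e^-w) Ve / (1/tau + sum r (1 - e^-w))
  m <- independent_pool(1000, 1, "e", 0.001)
  ce <- 1000 * 1e-3 * (1 - exp(-0.001))
  expect_equal(stationary_mean(m, p)$mean[[1]],
               ce * 60 / (1 / 15 + ce), tolerance = 1e-12)
  expect_equal(stationary_mean(m, p)$mean[[1]], 0.886, tolerance = 1e-3)
  ## monotone in rates: increasing inhibition lowers the mean
  m2 <- ensemble_model(100, 25, 10, 10, 0.01, 0.04)
  m3 <- ensemble_model(100, 25, 10, 20, 0.01, 0.04)
  expect_gt(stationary_mean(m2, p)$mean[[1]], stationary_mean(m3, p)$mean[[1]])
  expect_true(all(stationary_mean(m2, p)$mean > p$Vi &
                    stationary_mean(m2, p)$mean < p$Ve))
})

test_that("the triangular recursion reproduces the direct Palm formulas", {
  ## independent single-neuron route built from the count pmf (oracle)
  for (rho in c(0, 0.05, 0.3)) {
    K <- 120; r <- 2e-3; w <- 0.008
    pmf <- betabinomial_count_pmf(K, rho = rho)
    b <- pool_rate_oracle(K, 2, pmf) * 1e-3
    orc <- palm_moments_oracle(pmf, seq_len(K) * w, rep(0, K), b, p)
    model <- betabinomial_pool(K, 2, rho, weight = w)
    expect_equal(stationary_mean(model, p)$mean[[1]], orc$mean,
                 tolerance = 1e-12)
    expect_equal(stationary_variance(model, p), orc$variance,
                 tolerance = 1e-10)
    expect_equal(third_central_moment(model, p)$M3, orc$M3,
                 tolerance = 1e-9)
  }
})

test_that("centered moments equal binomial recentering of shifted moments", {
  m <- ensemble_model(20, 8, 6, 6, 0.02, 0.05, rho_e = 0.1, rho_i = 0.1,
                      rho_ei = 0.05)
  mu1 <- stationary_moment(m, p, 1)$shifted
  mu2 <- stationary_moment(m, p, c(1, 1))$shifted
  mu3 <- stationary_moment(m, p, c(1, 1, 1))$shifted
  expect_equal(stationary_moment(m, p, c(1, 1))$central, mu2 - mu1^2,
               tolerance = 1e-10)
  expect_equal(stationary_moment(m, p, c(1, 1, 1))$central,
               mu3 - 3 * mu2 * mu1 + 2 * mu1^3, tolerance = 1e-10)
})

test_that("enumerable toy models: engine matches event-driven simulation", {
  configs <- list(
    betabinomial_pool(3, 40, 0.2, "e", 0.05),
    ensemble_model(3, 2, 30, 30, 0.05, 0.1, rho_e = 0.3, rho_i = 0.2),
    ensemble_model(4, 2, 25, 25, 0.04, 0.08, rho_e = 0.2, rho_i = 0.2,
                   rho_ei = 0.1))
  for (ci in seq_along(configs)) {
    model <- configs[[ci]]
    dr <- sample_events(model, 4e5, seed = 100 + ci)
    tr <- simulate_event_driven(p, dr, 4e5, dt_ms = 5)
    st <- trace_statistics(tr, n_boot = 60)$neuron
    expect_lt(abs(st$mean - stationary_mean(model, p)$mean[[1]]),
              3 * st$se_mean)
    expect_lt(abs(st$variance - stationary_variance(model, p)),
              3 * st$se_variance)
    tm <- third_central_moment(model, p)
    expect_lt(abs(st$skewness - tm$skewness), 3 * st$se_skewness)
  }
})

test_that("pair moments: independence gives zero covariance, sharing does not", {
  ind <- mixture_model(
    independent_pool(20, 5, "e", 0.01, neurons = 1, n_neurons = 2),
    independent_pool(20, 5, "e", 0.01, neurons = 2, n_neurons = 2))
  expect_equal(stationary_covariance(ind, p)$covariance, 0, tolerance = 1e-14)
  sh <- shared_input_model(40, 10, 10, 10, 0.01, 0.04, fe = 0.5, fi = 0.5)
  sc <- stationary_covariance(sh, p)
  expect_gt(sc$covariance, 0)
  expect_lt(abs(sc$correlation), 1)
  ## setting both indices to the same neuron recovers the variance
  expect_equal(stationary_moment(sh, p, c(1, 1))$central, sc$variance[1],
               tolerance = 1e-12)
  ## simulation cross-check of the pair correlation
  tr <- simulate_event_driven(p, sample_events(sh, 3e5, seed = 55), 3e5,
                              dt_ms = 5)
  st <- trace_statistics(tr, n_boot = 60)
  expect_lt(abs(st$pairs$correlation - sc$correlation),
            3 * st$pairs$se_correlation)
})

test_that("third moments: skew directions and the compact-formula route", {
  ## inhibition alone at low rate: left-skewed
  mi <- independent_pool(100, 2, "i", 0.004)
  expect_lt(third_central_moment(mi, p)$skewness, 0)
  ## excitation alone just above 1/(2 tau) ~ 33 Hz: small negative skew
  me <- independent_pool(1000, 40, "e", 0.001)
  sk <- third_central_moment(me, p)$skewness
  expect_lt(sk, 0)
  expect_gt(sk, -0.2)
  ## the engine recursion agrees with the compact Palm-expectation formula
  ## (tolerance on the scale of variance^(3/2): the recentering of large
  ## shifted moments cancels catastrophically when M3 is near zero)
  for (model in list(me, betabinomial_pool(500, 2, 0.03, weight = 0.002),
                     ensemble_model(50, 20, 8, 8, 0.01, 0.04,
                                    rho_e = 0.1, rho_i = 0.1, rho_ei = 0.05))) {
    tm <- third_central_moment(model, p)
    expect_lt(abs(tm$M3 - aoncb:::third_moment_palm(model, p)),
              1e-6 * tm$variance^1.5)
  }
})

test_that("weak-weight and synchrony limits behave as the theory dictates", {
  ## variance and skewness vanish as weights shrink at fixed rates
  vars <- vapply(c(1e-2, 1e-3, 1e-4), function(w)
    stationary_variance(betabinomial_pool(100, 5, 0.1, weight = w), p), 0)
  expect_true(all(diff(vars) < 0))
  expect_lt(vars[3] / vars[1], 1e-3)
  ## skewness is scale-invariant: it converges to its small-weight limit
  ## (not to zero) as weights shrink at fixed rates
  sks <- vapply(c(1e-2, 1e-3, 1e-4), function(w)
    third_central_moment(betabinomial_pool(100, 5, 0.1, weight = w),
                         p)$skewness, 0)
  expect_lt(abs(sks[3] - sks[2]), abs(sks[2] - sks[1]))
  ## ... and vanishes in the large-drive (Gaussian) limit instead
  sk_hi <- third_central_moment(betabinomial_pool(1000, 100, 0, weight = 1e-4),
                                p)$skewness
  expect_lt(abs(sk_hi), 0.05)
  ## adding excitatory-inhibitory synchrony never increases the variance
  for (rho_ei in c(0.01, 0.03)) {
    v0 <- stationary_variance(
      ensemble_model(200, 50, 10, 10, 0.005, 0.02, 0.04, 0.04, 0), p)
    v1 <- stationary_variance(
      ensemble_model(200, 50, 10, 10, 0.005, 0.02, 0.04, 0.04, rho_ei), p)
    expect_lte(v1, v0)
  }
})
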