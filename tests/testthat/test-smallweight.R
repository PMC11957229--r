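p <- neuron_params()

## the standard weight/count constraints: Ke we = Ki wi = 1, wi = 4 we
std_spec <- function(re = 1, ri = 1, ...) {
  uniform_population_spec(Ke = 1000, Ki = 250, we = 0.001, wi = 0.004,
                          re = re, ri = ri, ..., params = p)
}

test_that("the excitation share q has its documented values and monotonicity", {
  sp <- std_spec()
  expect_equal(excitation_share_q(sp, m = 0), 0.9, tolerance = 1e-12)
  expect_equal(excitation_share_q(sp, m = 15), 2025 / (2025 + 2500),
               tolerance = 1e-12)
  ## q = 1 without inhibition
  spe <- uniform_population_spec(1000, 0, 0.001, 0, 1, 0, params = p)
  expect_equal(excitation_share_q(spe, m = 0), 1)
  ## decreasing in m over (Vi, Ve)
  qs <- vapply(seq(-5, 30, by = 5), function(m) excitation_share_q(sp, m), 0)
  expect_true(all(diff(qs) < 0))
})

test_that("kappa: excitation-only limit and the correlated-E/I values", {
  spe <- uniform_population_spec(1000, 0, 0.001, 0, 1, 0, params = p)
  expect_equal(kappa_ratio(spe, m = 0), 1000)
  sp <- std_spec()
  expect_equal(kappa_ratio(sp, m = 0) / 1000, 0.625, tolerance = 1e-12)
  expect_equal(kappa_ratio(sp, m = 15) / 1000, 0.0884, tolerance = 1e-2)
  ## independent-E/I case is the q-weighted pool-size average
  expect_equal(kappa_ratio(sp, m = 0, case = "independent_EI"),
               1000 * 0.9 + 250 * 0.1, tolerance = 1e-12)
  ## kappa is the exact ratio of the rho=1 to rho=0 small-weight variances
  for (m in c(0, 10, 15)) {
    v0 <- var_smallweight(std_spec(), m = m)
    v1 <- var_smallweight(std_spec(rho_e = 1, rho_i = 1, rho_ei = 1), m = m)
    expect_equal(v1 / v0, kappa_ratio(std_spec(), m = m), tolerance = 1e-6)
  }
})

test_that("variance: synchrony conditions order and decomposition identity", {
  sp <- std_spec(re = 10, ri = 10, rho_e = 0.03, rho_i = 0.03, rho_ei = 0.01)
  v_async <- var_smallweight(sp, "asynchronous")
  v_pool <- var_smallweight(sp, "pool_synchrony")
  v_full <- var_smallweight(sp)
  expect_gt(v_pool, v_async)        # pool synchrony only increases variance
  expect_lt(v_full, v_pool)         # E/I synchrony only decreases it
  ## uniform multiplier (1 + (K-1) rho) on each pool term
  spe <- uniform_population_spec(100, 0, 0.001, 0, 10, 0, rho_e = 0.05,
                                 params = p)
  expect_equal(var_smallweight(spe) / var_smallweight(spe, "asynchronous"),
               1 + 99 * 0.05, tolerance = 1e-12)
  ## M = (1 - rho) M|rho=0 + rho M|rho=1 in the uniform symmetric case
  rho <- 0.04; m <- 5
  base <- function(rr) std_spec(re = 10, ri = 10, rho_e = rr, rho_i = rr,
                                rho_ei = rr)
  expect_equal(var_smallweight(base(rho), m = m),
               (1 - rho) * var_smallweight(base(0), m = m) +
                 rho * var_smallweight(base(1), m = m),
               tolerance = 1e-10)
})

test_that("pair correlation: Eq-22 route equals the saturating-kappa route", {
  for (r in c(1, 5, 20, 50)) {
    sp <- std_spec(re = r, ri = r, rho_e = 0.02, rho_i = 0.02, rho_ei = 0.02,
                   rho_cross_ee = 0.013, rho_cross_ii = 0.013,
                   rho_cross_ei = 0.013)
    cs <- cov_smallweight(sp)
    expect_equal(cs$correlation,
                 corr_synchrony(0.02, 0.013, kappa_ratio(sp)),
                 tolerance = 1e-10)
  }
  ## no cross-neuron correlation, no covariance
  expect_equal(cov_smallweight(std_spec(rho_e = 0.02, rho_i = 0.02))$covariance,
               0)
  ## pure E/I cross-correlation makes the covariance negative
  spn <- std_spec(rho_e = 0.02, rho_i = 0.02, rho_ei = 0.02,
                  rho_cross_ei = 0.01)
  expect_lt(cov_smallweight(spn)$covariance, 0)
})

test_that("the saturating correlation respects its bound and regimes", {
  set.seed(7)
  for (i in 1:20) {
    rho <- runif(1, 0.01, 0.5)
    rhoc <- runif(1, 0, rho)
    kap <- runif(1, 1, 2000)
    rv <- corr_synchrony(rho, rhoc, kap)
    expect_lt(rv, rhoc / rho + 1e-12)
    expect_gte(rv, 0)
  }
  ## excitation only: linear in Ke below 1/rho, saturating far above
  rho <- 0.02; rhoc <- 0.013
  expect_equal(corr_synchrony(rho, rhoc, kappa = 5), rhoc * 5,
               tolerance = 0.15)
  expect_equal(corr_synchrony(rho, rhoc, kappa = 1e5), rhoc / rho,
               tolerance = 1e-2)
})

test_that("shared-input correlation formula behaves as documented", {
  sp <- std_spec(fe = 0.85, fi = 0.4)
  expect_equal(corr_shared_inputs(sp, m = 0), 0.85 * 0.9 + 0.4 * 0.1,
               tolerance = 1e-12)
  spe <- uniform_population_spec(1000, 0, 0.001, 0, 1, 0, fe = 0.6,
                                 params = p)
  expect_equal(corr_shared_inputs(spe, m = 0), 0.6)   # excitation only: fe
  spf <- std_spec(fe = 0.3, fi = 0.3)
  expect_equal(corr_shared_inputs(spf, m = 7), 0.3, tolerance = 1e-12)
})

test_that("closed-form skewness: reference values, synchrony factor, root", {
  s1 <- skewness_excitation(1000, 1, 15, 0)
  expect_equal(s1$S_ref, 2 * sqrt(2) / (3 * sqrt(15)), tolerance = 1e-12)
  expect_equal(s1$S, s1$S_ref * (1 - 2 * 0.015) / 1.015, tolerance = 1e-12)
  s2 <- skewness_excitation(1000, 1, 15, 0.03)
  expect_equal(s2$S / s1$S, sqrt(1 + 0.03 * 1000), tolerance = 1e-12)
  ## drive factor vanishes at re = 1/(2 tau)
  s3 <- skewness_excitation(1000, 1000 / (2 * 15), 15, 0.1)
  expect_equal(s3$S, 0, tolerance = 1e-12)
})

test_that("the third-moment display converges to the exact engine as O(w)", {
  m3_errs <- function(rho) vapply(c(1e-2, 1e-3, 1e-4), function(w) {
    K <- round(1 / w)
    model <- betabinomial_pool(K, 1, rho, weight = w)
    exact <- third_central_moment(model, p)
    disp <- excitation_only_third_moment(K, 1, w, 15, rho,
                                         m = exact$mean[[1]])
    abs(disp - exact$M3) / abs(exact$M3)
  }, 0)
  ## asynchronous: clean O(w) decrease
  e0 <- m3_errs(0)
  expect_true(all(diff(e0) < 0))
  expect_lt(e0[3], 0.01)
  expect_lt(e0[2] / e0[1], 0.15)   # roughly one decade per decade of w
  ## synchrony keeps O(1) jumps alive at fixed K w: the error decreases to a
  ## nonzero plateau set by the synchronous jump tail
  es <- m3_errs(0.03)
  expect_true(all(diff(es) < 0))
  expect_lt(es[3], 0.15)
  ## single asynchronous input: plain shot-noise third moment
  ex1 <- third_central_moment(independent_pool(1, 20, "e", 1e-4), p)
  expect_equal(excitation_only_third_moment(1, 20, 1e-4, 15, 0,
                                            m = ex1$mean[[1]]),
               ex1$M3, tolerance = 1e-3)
})

test_that("small-weight variance/covariance converge to the exact engine", {
  var_err <- function(rho, w) {
    K <- round(1 / w)
    model <- ensemble_model(K, K / 4, 5, 5, w, 4 * w, rho_e = rho,
                            rho_i = rho)
    sp <- uniform_population_spec(K, K / 4, w, 4 * w, 5, 5, rho_e = rho,
                                  rho_i = rho, params = p)
    v_ex <- stationary_variance(model, p)
    abs(var_smallweight(sp, m = stationary_mean(model, p)$mean[[1]]) - v_ex) /
      v_ex
  }
  ## asynchronous: O(w) convergence
  e0 <- vapply(c(1e-2, 1e-3, 1e-4), function(w) var_err(0, w), 0)
  expect_true(all(diff(e0) < 0))
  expect_lt(e0[3], 1e-3)
  ## synchronous: decreasing toward a small plateau (jump-tail bias)
  es <- vapply(c(1e-2, 1e-3, 1e-4), function(w) var_err(0.03, w), 0)
  expect_true(all(diff(es) < 0))
  expect_lt(es[3], 0.07)
  ## shared asynchronous inputs: engine versus fe q + fi (1-q)
  model <- shared_input_model(400, 100, 5, 5, 0.001, 0.004,
                              fe = 0.85, fi = 0.4)
  sc <- stationary_covariance(model, p)
  sp <- uniform_population_spec(400, 100, 0.001, 0.004, 5, 5,
                                fe = 0.85, fi = 0.4, params = p)
  expect_equal(sc$correlation, corr_shared_inputs(sp, m = sc$mean[1]),
               tolerance = 0.02)
})

test_that("count-compensated faulty transmission preserves the statistics", {
  sp <- std_spec(re = 10, ri = 10, rho_e = 0.03, rho_i = 0.03)
  chk <- faulty_scaling_check(sp, 1)
  expect_equal(chk$variance_mV2[1], chk$variance_mV2[2], tolerance = 1e-14)
  chk <- faulty_scaling_check(sp, 0.1)
  expect_equal(chk$mean_mV[2], chk$mean_mV[1], tolerance = 1e-12)
  ## variance and skewness are preserved to O(rho (1-p) / K): the exact
  ## multiplier carries (K-1), not K
  expect_equal(chk$variance_mV2[2], chk$variance_mV2[1], tolerance = 2e-3)
  expect_equal(chk$skewness_excitation[2], chk$skewness_excitation[1],
               tolerance = 5e-2)
  ## weight compensation inflates the asynchronous variance term
  expect_gt(chk$variance_mV2[3], chk$variance_mV2[1])
})
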