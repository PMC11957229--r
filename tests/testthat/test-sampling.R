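test_that("sampled event drives have the right rate and jump structure", {
  ## zero-rate model: empty drive
  z <- independent_pool(3, 0, "e", 0.01)
  expect_length(sample_events(z, 1000, seed = 1)$time_ms, 0)
  ## single asynchronous input at 10 Hz over 100 s: ~1000 events of size w
  m1 <- independent_pool(1, 10, "e", 0.02)
  d <- sample_events(m1, 1e5, seed = 2)
  expect_gt(length(d$time_ms), 1000 - 3 * sqrt(1000))
  expect_lt(length(d$time_ms), 1000 + 3 * sqrt(1000))
  expect_true(all(d$We == 0.02))
  ## beta-binomial pool: event count matches the collective rate
  bb <- betabinomial_pool(100, 1, 0.03, weight = 0.001)
  db <- sample_events(bb, 2e5, seed = 3)
  lam <- betabinomial_event_rate(100, 1, 0.03) * 1e-3 * 2e5
  expect_lt(abs(length(db$time_ms) - lam), 3 * sqrt(lam))
  ## jumps are multiples of the weight
  expect_true(all(abs(db$We / 0.001 - round(db$We / 0.001)) < 1e-9))
})

test_that("sampled trains reproduce per-input rates and pattern frequencies", {
  toy <- betabinomial_pool(3, 5, 0.2, "e", 0.02)
  tr <- sample_spike_trains(toy, 2e5, seed = 7)
  ## per-input empirical rates within 3 SE of 5 Hz
  for (id in 1:3) {
    n_id <- sum(tr$input_id == id)
    expect_lt(abs(n_id - 1000), 3 * sqrt(1000))
  }
  ## per-event patterns match the enumerated law (3-SE band per pattern)
  pp <- pattern_pmf(toy)
  ev <- split(tr$input_id, tr$time_ms)
  n_ev <- length(ev)
  key_obs <- vapply(ev, function(ids) paste(sort(ids), collapse = "-"), "")
  key_ref <- apply(pp$patterns, 1, function(x) paste(which(x), collapse = "-"))
  for (i in seq_along(key_ref)) {
    obs <- sum(key_obs == key_ref[i])
    expd <- n_ev * pp$prob[i]
    expect_lt(abs(obs - expd), 3 * sqrt(expd) + 3)
  }
})

test_that("empirical binned correlation at fine timescales matches the model", {
  bb <- betabinomial_pool(40, 2, 0.1, weight = 0.001)
  tr <- sample_spike_trains(bb, 3e5, seed = 11)
  rho_hat <- binned_spiking_correlation(tr, 2, 3e5)
  expect_lt(abs(rho_hat - 0.1), 0.01)
})

test_that("jitter preserves counts, erases fine-timescale correlation", {
  bb <- betabinomial_pool(30, 5, 0.25, weight = 0.001)
  tr <- sample_spike_trains(bb, 1e5, seed = 21, pad_ms = 300)
  ## sigma = 0 is the identity
  expect_identical(jitter_spikes(tr, 0), tr)
  ## jitter without cropping preserves every spike
  expect_equal(nrow(jitter_spikes(tr, 20, seed = 1)), nrow(tr))
  ## binned correlation decreases with jitter at fixed bin width,
  ## and for jittered trains decreases with finer bins
  rho <- sapply(c(0, 10, 40), function(s) {
    jt <- jitter_spikes(tr, s, seed = 22, crop = c(0, 1e5))
    binned_spiking_correlation(jt, 25, 1e5)
  })
  expect_true(all(diff(rho) < 0))
  jt <- jitter_spikes(tr, 40, seed = 23, crop = c(0, 1e5))
  rho_dt <- sapply(c(5, 25, 100), function(dt)
    binned_spiking_correlation(jt, dt, 1e5))
  expect_true(all(diff(rho_dt) > 0))  # vanishing as dt -> 0
  expect_error(binned_spiking_correlation(tr, 2e5, 1e5), "exceeds")
})

test_that("faulty transmission thins rates and correlations as r' = pr, rho' = p rho", {
  bb <- betabinomial_pool(50, 10, 0.2, weight = 0.002)
  expect_identical(apply_faulty_transmission(bb, 1), bb)
  th <- apply_faulty_transmission(bb, 0.3)
  expect_equal(event_rate(th, inputs = 1), 3, tolerance = 1e-10)
  expect_equal(spiking_correlation(th, 1:2), 0.3 * 0.2, tolerance = 1e-10)
  ## third-order coefficient also transforms correctly: rho3' = p^2 rho3
  expect_equal(spiking_correlation(th, 1:3),
               0.3^2 * betabinomial_correlation(0.2, 3), tolerance = 1e-10)
  ## train-level thinning: empirical rate p*r
  tr <- sample_spike_trains(bb, 1e5, seed = 31)
  trt <- apply_faulty_transmission(tr, 0.3, seed = 32)
  expect_lt(abs(nrow(trt) - 0.3 * nrow(tr)), 3 * sqrt(0.3 * nrow(tr)))
  expect_error(apply_faulty_transmission(bb, 0), "degenerate")
})

test_that("weight and count compensation act as documented", {
  bb <- betabinomial_pool(50, 10, 0.2, weight = 0.002)
  thw <- apply_faulty_transmission(bb, 0.5, compensate = "weights")
  expect_equal(max(thw$input_table$weights), 0.004, tolerance = 1e-12)
  thc <- apply_faulty_transmission(bb, 0.5, compensate = "counts")
  expect_equal(length(thc$input_table$id), 100)
  expect_equal(event_rate(thc, inputs = 1), 5, tolerance = 1e-10)
  expect_equal(spiking_correlation(thc, 1:2), 0.1, tolerance = 1e-10)
})

test_that("drives rebuilt from trains match directly sampled statistics", {
  m <- ensemble_model(10, 4, 8, 8, 0.01, 0.04, rho_e = 0.1, rho_i = 0.1,
                      rho_ei = 0.05)
  tr <- sample_spike_trains(m, 5e4, seed = 41)
  d <- drive_from_trains(tr)
  ## total conductance mass is conserved spike by spike
  expect_equal(sum(d$We), 0.01 * sum(tr$pool == "e"), tolerance = 1e-9)
  expect_equal(sum(d$Wi), 0.04 * sum(tr$pool == "i"), tolerance = 1e-9)
  ## synchronous events aggregate several spikes
  expect_lt(length(d$time_ms), nrow(tr))
})
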