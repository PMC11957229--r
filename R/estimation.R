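## Empirical statistics, PASTA validation, experiment presets -----------------

#' Stationary statistics of a simulated voltage trace
#'
#' Mean, variance and skewness per neuron and covariance/correlation per
#' neuron pair, estimated from the post-burn-in samples of a voltage trace,
#' with standard errors from a moving-block bootstrap (block length of ten
#' membrane time constants, matching the voltage autocorrelation scale).
#'
#' @param trace a `"voltage_trace"`.
#' @param burn_in_ms samples before this time are discarded; defaults to
#'   `max(10 tau, 50/b)` with `b` the empirical event rate.
#' @param block_ms bootstrap block length, ms.
#' @param n_boot number of bootstrap replicates.
#' @return A list of class `"trace_statistics"`: `neuron` (data frame with
#'   `mean`, `variance`, `skewness` and their SEs), `pairs` (data frame with
#'   `covariance`, `correlation` and SEs), `burn_in_ms`, `n_samples`.
#' @examples
#' m <- independent_pool(100, 10, "e", 0.01)
#' tr <- simulate_event_driven(neuron_params(),
#'                             sample_events(m, 30000, seed = 1), 30000)
#' trace_statistics(tr)$neuron
#' @export
trace_statistics <- function(trace, burn_in_ms = NULL, block_ms = NULL,
                             n_boot = 200) {
  stopifnot(inherits(trace, "voltage_trace"))
  tau_max <- max(vapply(trace$params, `[[`, 0, "tau"))
  span <- diff(range(trace$time_ms))
  if (is.null(burn_in_ms)) {
    b_emp <- if (!is.null(trace$events) && length(trace$events$time_ms) > 1)
      length(trace$events$time_ms) / span else Inf
    burn_in_ms <- max(10 * tau_max, 50 / b_emp)
  }
  keep <- trace$time_ms >= burn_in_ms
  if (span - burn_in_ms < 100 * tau_max)
    stop(sprintf("trace too short: need >= %g ms after burn-in, have %g",
                 100 * tau_max, max(span - burn_in_ms, 0)), call. = FALSE)
  V <- trace$V[keep, , drop = FALSE]
  n <- ncol(V); ns <- nrow(V)
  if (is.null(block_ms)) block_ms <- 10 * tau_max
  dt <- mean(diff(trace$time_ms))
  block_len <- max(1L, round(block_ms / dt))
  n_blocks <- floor(ns / block_len)
  stat_fun <- function(Vs) {
    mu <- colMeans(Vs)
    ctr <- sweep(Vs, 2, mu)
    v <- colMeans(ctr^2)
    sk <- ifelse(v > 0, colMeans(ctr^3) / v^1.5, NA_real_)
    covs <- NULL
    if (n >= 2) {
      pr <- utils::combn(n, 2)
      covs <- apply(pr, 2, function(ij) {
        cv <- mean(ctr[, ij[1]] * ctr[, ij[2]])
        c(cv, cv / sqrt(v[ij[1]] * v[ij[2]]))
      })
    }
    list(mean = mu, variance = v, skewness = sk, pairs = covs)
  }
  est <- stat_fun(V)
  ## moving-block bootstrap
  boot <- replicate(n_boot, {
    starts <- sample.int(ns - block_len + 1L, n_blocks, replace = TRUE)
    idx <- as.vector(outer(seq_len(block_len) - 1L, starts, `+`))
    stat_fun(V[idx, , drop = FALSE])
  }, simplify = FALSE)
  se_of <- function(get) apply(do.call(rbind, lapply(boot, get)), 2, sd)
  neuron <- data.frame(neuron = seq_len(n), mean = est$mean,
                       variance = est$variance, skewness = est$skewness,
                       se_mean = se_of(function(x) x$mean),
                       se_variance = se_of(function(x) x$variance),
                       se_skewness = se_of(function(x) x$skewness))
  pairs <- NULL
  if (n >= 2) {
    pr <- utils::combn(n, 2)
    cov_boot <- do.call(rbind, lapply(boot, function(x) x$pairs[1, ]))
    cor_boot <- do.call(rbind, lapply(boot, function(x) x$pairs[2, ]))
    pairs <- data.frame(neuron_a = pr[1, ], neuron_b = pr[2, ],
                        covariance = est$pairs[1, ],
                        correlation = est$pairs[2, ],
                        se_covariance = apply(cov_boot, 2, sd),
                        se_correlation = apply(cor_boot, 2, sd))
  }
  structure(list(neuron = neuron, pairs = pairs, burn_in_ms = burn_in_ms,
                 n_samples = ns, block_ms = block_ms),
            class = "trace_statistics")
}

#' PASTA validation: pre-event versus typical-time voltage samples
#'
#' For a stationary process driven by Poisson event arrivals, the voltage
#' distribution sampled just before events equals the distribution sampled
#' at uniformly spaced times ("Poisson arrivals see time averages").  This
#' check computes, per neuron, the Kolmogorov-Smirnov distance between the
#' post-burn-in grid samples and the pre-event samples `V(T-)` and compares
#' it with a threshold.  Non-Poisson (e.g. periodic) drives violate the
#' equivalence and fail the check.
#'
#' @param trace a `"voltage_trace"` with event anchors.
#' @param burn_in_ms burn-in, ms (default ten membrane time constants).
#' @param threshold maximal admissible KS distance.
#' @return A list with `distance` (per neuron), `pass` (logical), and the
#'   sample sizes used.
#' @export
pasta_check <- function(trace, burn_in_ms = NULL, threshold = 0.1) {
  stopifnot(inherits(trace, "voltage_trace"))
  if (is.null(trace$events) || is.null(trace$events$V_pre))
    stop("trace has no pre-event voltage anchors", call. = FALSE)
  tau_max <- max(vapply(trace$params, `[[`, 0, "tau"))
  if (is.null(burn_in_ms)) burn_in_ms <- 10 * tau_max
  gsel <- trace$time_ms >= burn_in_ms
  esel <- trace$events$time_ms >= burn_in_ms
  n_ev <- sum(esel)
  if (n_ev < 100)
    stop("need at least 100 post-burn-in events for the PASTA check",
         call. = FALSE)
  if (n_ev < 1000)
    warning("fewer than 1000 post-burn-in events; the PASTA distance is noisy",
            call. = FALSE)
  d <- vapply(seq_len(ncol(trace$V)), function(a) {
    suppressWarnings(unname(
      ks.test(trace$V[gsel, a], trace$events$V_pre[esel, a])$statistic))
  }, 0)
  list(distance = d, pass = all(d <= threshold), threshold = threshold,
       n_grid = sum(gsel), n_events = n_ev)
}

## Experiment presets ---------------------------------------------------------

#' Desk-scale experiment presets
#'
#' Runs one of the package's named parameter sweeps and returns a tidy data
#' frame (one row per grid point and engine).  Presets mirror the standard
#' study conditions of the synchrony analysis:
#'
#' * `"epsilon_convergence"`: stationary mean/variance of the finite-`tau_s`
#'   integrator versus the exact event-driven scheme for
#'   `tau_s = 2, 0.2, 0.02` ms.
#' * `"variance_vs_rate"`: exact and small-weight variance versus drive rate
#'   under asynchronous, pool-synchronous and jointly synchronous input.
#' * `"shared_inputs"`: voltage correlation of two neurons sharing
#'   asynchronous inputs (`Ke = 200`, `fe = 0.85`, `Ki = 50`, `fi = 0.4`,
#'   large weights), at resting (1 Hz) and driven (50 Hz) rates.
#' * `"correlation_vs_rate"`: voltage correlation of two synchronously
#'   driven neurons (`Ke = 1000`, `Ki = 250`, moderate weights,
#'   `rho = 0.02`, `rho' = 0.013`) versus drive rate.
#' * `"skewness_vs_rate"`: exact skewness versus rate for excitation alone,
#'   inhibition alone and joint drive, with and without synchrony.
#' * `"jitter_consistency"`: binned spiking correlation of jittered
#'   synchronous trains versus bin width.
#' * `"decorrelation_external_drive"`: pair voltage correlation versus the
#'   rate of an additional uncorrelated excitatory drive.
#'
#' @param preset preset name (see above).
#' @param scale `"desk"` (default) or `"full"`; full scale lengthens
#'   simulated durations about tenfold.
#' @param seed integer seed for the stochastic presets.
#' @param out_dir optional directory; when given, the result table is
#'   written as `<preset>.csv` beside a small run manifest
#'   `<preset>_manifest.csv` (preset, scale, seed, package version), making
#'   re-runs bit-reproducible and self-describing.
#' @return A data frame; attributes record the preset and seed.
#' @examples
#' head(run_experiment("correlation_vs_rate"))
#' @export
run_experiment <- function(preset = c("epsilon_convergence", "variance_vs_rate",
                                      "shared_inputs", "correlation_vs_rate",
                                      "skewness_vs_rate", "jitter_consistency",
                                      "decorrelation_external_drive"),
                           scale = c("desk", "full"), seed = 1,
                           out_dir = NULL) {
  preset <- match.arg(preset)
  scale <- match.arg(scale)
  fac <- if (scale == "desk") 1 else 10
  out <- switch(preset,
    epsilon_convergence = exp_epsilon_convergence(seed, fac),
    variance_vs_rate = exp_variance_vs_rate(),
    shared_inputs = exp_shared_inputs(),
    correlation_vs_rate = exp_correlation_vs_rate(),
    skewness_vs_rate = exp_skewness_vs_rate(),
    jitter_consistency = exp_jitter_consistency(seed, fac),
    decorrelation_external_drive = exp_decorrelation())
  attr(out, "preset") <- preset
  attr(out, "seed") <- seed
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(out, file.path(out_dir, paste0(preset, ".csv")),
              row.names = FALSE)
    manifest <- data.frame(preset = preset, scale = scale, seed = seed,
                           package_version = as.character(
                             utils::packageVersion("aoncb")),
                           r_version = as.character(getRversion()))
    write.csv(manifest, file.path(out_dir, paste0(preset, "_manifest.csv")),
              row.names = FALSE)
  }
  out
}

exp_epsilon_convergence <- function(seed, fac) {
  model <- ensemble_model(Ke = 100, Ki = 25, re = 10, ri = 10,
                          we = 0.01, wi = 0.04, rho_e = 0.03, rho_i = 0.06)
  dur <- 20000 * fac
  drive <- sample_events(model, dur, seed)
  p <- neuron_params()
  rows <- lapply(c(2, 0.2, 0.02), function(ts) {
    tr <- simulate_finite_tau_s(p, drive, ts, dur, dt_ms = 2)
    st <- trace_statistics(tr, n_boot = 50)
    data.frame(tau_s_ms = ts, mean_mV = st$neuron$mean,
               variance_mV2 = st$neuron$variance)
  })
  tr0 <- simulate_event_driven(p, drive, dur, dt_ms = 2)
  st0 <- trace_statistics(tr0, n_boot = 50)
  out <- rbind(do.call(rbind, rows),
               data.frame(tau_s_ms = 0, mean_mV = st0$neuron$mean,
                          variance_mV2 = st0$neuron$variance))
  out$exact_mean_mV <- stationary_mean(model, p)$mean[1]
  out$exact_variance_mV2 <- stationary_variance(model, p)
  out
}

exp_variance_vs_rate <- function() {
  p <- neuron_params()
  grid <- expand.grid(rate_hz = c(1, 5, 10, 20, 30),
                      condition = c("asynchronous", "pool_synchrony",
                                    "ei_synchrony"),
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    r <- grid$rate_hz[i]; cond <- grid$condition[i]
    rho_e <- if (cond == "asynchronous") 0 else 0.03
    rho_i <- if (cond == "asynchronous") 0 else 0.06
    rho_ei <- if (cond == "ei_synchrony") sqrt(rho_e * rho_i) / 2 else 0
    model <- ensemble_model(1000, 250, r, r, 0.001, 0.004,
                            rho_e, rho_i, rho_ei)
    sp <- uniform_population_spec(1000, 250, 0.001, 0.004, r, r,
                                  rho_e, rho_i, rho_ei, params = p)
    data.frame(rate_hz = r, condition = cond,
               variance_exact = stationary_variance(model, p),
               variance_smallweight = var_smallweight(sp),
               mean_exact = stationary_mean(model, p)$mean[1])
  })
  do.call(rbind, rows)
}

exp_shared_inputs <- function() {
  p <- neuron_params()
  rows <- lapply(c(1, 10, 25, 50), function(r) {
    model <- shared_input_model(200, 50, r, r, 0.01, 0.04, fe = 0.85, fi = 0.4)
    sc <- stationary_covariance(model, p)
    sp <- uniform_population_spec(200, 50, 0.01, 0.04, r, r,
                                  fe = 0.85, fi = 0.4, params = p)
    data.frame(rate_hz = r, correlation_exact = sc$correlation,
               correlation_smallweight = corr_shared_inputs(sp),
               mean_mV = sc$mean[1], variance_mV2 = sc$variance[1])
  })
  do.call(rbind, rows)
}

exp_correlation_vs_rate <- function() {
  p <- neuron_params()
  targets <- list(rho_e = 0.02, rho_i = 0.02, rho_ei = 0.02,
                  rho_cross_ee = 0.013, rho_cross_ii = 0.013,
                  rho_cross_ei = 0.013)
  rows <- lapply(c(1, 5, 10, 20, 50), function(r) {
    sp <- uniform_population_spec(1000, 250, 0.001, 0.004, r, r,
                                  rho_e = 0.02, rho_i = 0.02, rho_ei = 0.02,
                                  rho_cross_ee = 0.013, rho_cross_ii = 0.013,
                                  rho_cross_ei = 0.013, params = p)
    sw <- cov_smallweight(sp)
    kap <- kappa_ratio(sp)
    model <- calibrate_mixture(targets, 1000, 250, r, r, 0.001, 0.004)
    sc <- stationary_covariance(model, p)
    data.frame(rate_hz = r,
               correlation_smallweight = sw$correlation,
               correlation_saturating = corr_synchrony(0.02, 0.013, kap),
               correlation_exact = sc$correlation,
               mean_mV = sw$m)
  })
  do.call(rbind, rows)
}

exp_skewness_vs_rate <- function() {
  p <- neuron_params()
  grid <- expand.grid(rate_hz = c(1, 5, 10, 25, 50),
                      drive = c("e_only", "i_only", "both"),
                      synchrony = c(0, 0.03), stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    r <- grid$rate_hz[i]; rho <- grid$synchrony[i]
    Ke <- if (grid$drive[i] == "i_only") 0 else 1000
    Ki <- if (grid$drive[i] == "e_only") 0 else 250
    model <- ensemble_model(Ke, Ki, r, r, 0.001, 0.004,
                            rho_e = if (Ke) rho else 0,
                            rho_i = if (Ki) rho else 0)
    tm <- third_central_moment(model, p)
    data.frame(rate_hz = r, drive = grid$drive[i], rho = rho,
               skewness_exact = tm$skewness, variance_mV2 = tm$variance)
  })
  do.call(rbind, rows)
}

exp_jitter_consistency <- function(seed, fac) {
  model <- betabinomial_pool(50, 10, 0.25, weight = 0.001)
  dur <- 100000 * fac
  tr <- sample_spike_trains(model, dur, seed, pad_ms = 300)
  jt <- jitter_spikes(tr, 50, seed = seed + 1, crop = c(0, dur))
  rows <- lapply(c(5, 10, 25, 50, 100), function(dt) {
    data.frame(delta_t_ms = dt,
               rho_unjittered = binned_spiking_correlation(tr, dt, dur),
               rho_jittered = binned_spiking_correlation(jt, dt, dur))
  })
  do.call(rbind, rows)
}

exp_decorrelation <- function() {
  p <- neuron_params()
  targets <- list(rho_e = 0.03, rho_i = 0.03,
                  rho_cross_ee = 0.025, rho_cross_ii = 0.025)
  base <- calibrate_mixture(targets, 1000, 250, 5, 5, 0.001, 0.004)
  rows <- lapply(c(0, 5, 10, 20, 40), function(rx) {
    model <- if (rx == 0) base else
      mixture_model(base,
                    independent_pool(400, rx, "e", 0.001, neurons = 1,
                                     n_neurons = 2),
                    independent_pool(400, rx, "e", 0.001, neurons = 2,
                                     n_neurons = 2))
    sc <- stationary_covariance(model, p)
    data.frame(external_rate_hz = rx, correlation = sc$correlation,
               variance_mV2 = sc$variance[1])
  })
  do.call(rbind, rows)
}

## Fixtures -------------------------------------------------------------------

#' Deterministic fixtures for tests and demonstrations
#'
#' Produces small, fully reproducible objects: an enumerable three-input
#' model with its exact pattern table, a hand-specified three-event drive
#' together with its closed-form (piecewise exponential + Marcus jump)
#' golden voltage values, and a short sampled spike-train set.
#'
#' @param seed integer seed for the sampled trains.
#' @return A list with `toy_model`, `pattern_table`, `drive`,
#'   `golden_times_ms`, `golden_V`, `trains`.
#' @export
generate_fixtures <- function(seed = 1) {
  toy <- betabinomial_pool(3, 5, 0.2, "e", 0.02)
  toy$label <- "toy 3-input model"
  pp <- pattern_pmf(toy)
  pattern_table <- data.frame(pp$patterns, prob = pp$prob)
  ## three-event drive and its closed-form solution at selected times
  p <- neuron_params()
  drive <- event_drive(c(20, 45, 80),
                       We = c(0.05, 0, 0.1), Wi = c(0, 0.2, 0.05))
  golden_times <- c(10, 30, 60, 100)
  seg_value <- function(t) {
    v <- p$rest
    t_prev <- 0
    for (i in seq_along(drive$time_ms)) {
      te <- drive$time_ms[i]
      if (t < te) break
      v <- p$rest + (v - p$rest) * exp(-(te - t_prev) / p$tau)
      we <- drive$We[i, 1]; wi <- drive$Wi[i, 1]
      s <- we + wi
      v <- v + ((we * p$Ve + wi * p$Vi) / s - v) * (1 - exp(-s))
      t_prev <- te
    }
    p$rest + (v - p$rest) * exp(-(t - t_prev) / p$tau)
  }
  golden_V <- vapply(golden_times, seg_value, 0)
  trains <- sample_spike_trains(toy, 2000, seed)
  list(toy_model = toy, pattern_table = pattern_table, drive = drive,
       golden_times_ms = golden_times, golden_V = golden_V, trains = trains)
}
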