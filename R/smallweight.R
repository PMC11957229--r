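## Small-weight closed forms ---------------------------------------------------
##
## Leading-order expansions of the exact moment formulas in the dimensionless
## synaptic weights, for two symmetric neurons driven by uniform pools:
## interpretable expressions in terms of input rates and pairwise spiking
## correlations only.

#' Uniform two-pool population specification for the small-weight theory
#'
#' Describes one neuron (or two statistically identical neurons) driven by
#' `Ke` excitatory and `Ki` inhibitory inputs with uniform weights, rates and
#' correlation structure.  Within-neuron pairwise spiking correlations are
#' `rho_e`, `rho_i` (same pool) and `rho_ei` (across pools); across-neuron
#' correlations are `rho_cross_ee`, `rho_cross_ii`, `rho_cross_ei`; shared
#' fractions `fe`, `fi` describe common asynchronous inputs.  Correlations
#' must satisfy `rho_cross <= rho` and `rho_ei <= sqrt(rho_e rho_i)`.
#'
#' @param Ke,Ki pool sizes.
#' @param we,wi dimensionless weights (a warning is issued above 0.05, where
#'   the small-weight expansion degrades).
#' @param re,ri per-input rates, Hz.
#' @param rho_e,rho_i,rho_ei within-neuron pairwise correlations.
#' @param rho_cross_ee,rho_cross_ii,rho_cross_ei across-neuron correlations.
#' @param fe,fi shared input fractions in `[0, 1]`.
#' @param params a [neuron_params()].
#' @return An object of class `"uniform_population_spec"`.
#' @examples
#' uniform_population_spec(Ke = 1000, Ki = 250, we = 0.001, wi = 0.004,
#'                         re = 1, ri = 1, rho_e = 0.02, rho_i = 0.02,
#'                         rho_ei = 0.02, rho_cross_ee = 0.013,
#'                         rho_cross_ii = 0.013, rho_cross_ei = 0.013)
#' @export
uniform_population_spec <- function(Ke, Ki, we, wi, re, ri,
                                    rho_e = 0, rho_i = 0, rho_ei = 0,
                                    rho_cross_ee = 0, rho_cross_ii = 0,
                                    rho_cross_ei = 0, fe = 0, fi = 0,
                                    params = neuron_params()) {
  stopifnot(Ke >= 0, Ki >= 0, we >= 0, wi >= 0, re >= 0, ri >= 0,
            fe >= 0, fe <= 1, fi >= 0, fi <= 1)
  check_corr_targets(rho_e, rho_i, rho_ei)
  for (nm in c("rho_cross_ee", "rho_cross_ii", "rho_cross_ei")) {
    v <- get(nm)
    if (v < 0 || v > 1) stop(nm, " must lie in [0, 1]", call. = FALSE)
  }
  if (rho_cross_ee > rho_e + 1e-12 || rho_cross_ii > rho_i + 1e-12)
    stop("across-neuron correlation must not exceed within-neuron (rho' <= rho)",
         call. = FALSE)
  if (max(we, wi) > 0.05)
    warning("weights above 0.05: small-weight approximation may be inaccurate",
            call. = FALSE)
  structure(list(Ke = Ke, Ki = Ki, we = we, wi = wi, re = re, ri = ri,
                 rho_e = rho_e, rho_i = rho_i, rho_ei = rho_ei,
                 rho_cross_ee = rho_cross_ee, rho_cross_ii = rho_cross_ii,
                 rho_cross_ei = rho_cross_ei, fe = fe, fi = fi,
                 params = params),
            class = "uniform_population_spec")
}

## classical efficacies (per ms) and the effective-time-constant denominator
sw_rates <- function(spec) {
  list(ce = spec$Ke * spec$re * HZ * spec$we,
       ci = spec$Ki * spec$ri * HZ * spec$wi)
}

#' Self-consistent small-weight stationary mean
#'
#' Mean voltage from the stationary-mean formula with the classical
#' small-weight efficacies `c_alpha = K_alpha r_alpha w_alpha`:
#' `m = (c_e Ve + c_i Vi + rest/tau) / (1/tau + c_e + c_i)`.
#'
#' @param spec a [uniform_population_spec()].
#' @return Mean voltage, mV.
#' @export
smallweight_mean <- function(spec) {
  p <- spec$params
  cc <- sw_rates(spec)
  (cc$ce * p$Ve + cc$ci * p$Vi + p$rest / p$tau) / (1 / p$tau + cc$ce + cc$ci)
}

#' Small-weight stationary voltage variance under a synchrony condition
#'
#' Leading-order variance of one neuron's stationary voltage:
#' \deqn{M \simeq \frac{\sum_\alpha (V_\alpha - m)^2 K_\alpha r_\alpha
#'   (1 + (K_\alpha - 1)\rho_\alpha) w_\alpha^2 -
#'   2 (V_e - m)(m - V_i) \rho_{ei} K_e K_i \sqrt{r_e r_i} w_e w_i}
#'   {2 (1/\tau + \sum_\alpha K_\alpha r_\alpha w_\alpha)}.}
#' `condition = "asynchronous"` forces all correlations to zero,
#' `"pool_synchrony"` keeps `rho_e`, `rho_i` but drops `rho_ei`, and
#' `"ei_synchrony"` (the default, `"auto"`) uses the full specification.
#' Pool synchrony can only increase the variance; excitatory-inhibitory
#' synchrony can only decrease it.
#'
#' @param spec a [uniform_population_spec()].
#' @param condition synchrony condition (see above).
#' @param m mean voltage override, mV; defaults to [smallweight_mean()].
#' @return Variance in mV^2.
#' @examples
#' sp <- uniform_population_spec(1000, 250, 0.001, 0.004, 10, 10,
#'                               rho_e = 0.03, rho_i = 0.03)
#' var_smallweight(sp)
#' @export
var_smallweight <- function(spec,
                            condition = c("auto", "asynchronous",
                                          "pool_synchrony", "ei_synchrony"),
                            m = NULL) {
  condition <- match.arg(condition)
  p <- spec$params
  if (is.null(m)) m <- smallweight_mean(spec)
  rho_e <- spec$rho_e; rho_i <- spec$rho_i; rho_ei <- spec$rho_ei
  if (condition == "asynchronous") { rho_e <- rho_i <- rho_ei <- 0 }
  if (condition == "pool_synchrony") rho_ei <- 0
  cc <- sw_rates(spec)
  denom <- 2 * (1 / p$tau + cc$ce + cc$ci)
  num_e <- (p$Ve - m)^2 * spec$Ke * spec$re * HZ *
    (1 + (spec$Ke - 1) * rho_e) * spec$we^2
  num_i <- (p$Vi - m)^2 * spec$Ki * spec$ri * HZ *
    (1 + (spec$Ki - 1) * rho_i) * spec$wi^2
  num_ei <- 2 * (p$Ve - m) * (p$Vi - m) * rho_ei *
    spec$Ke * spec$Ki * sqrt(spec$re * HZ * spec$ri * HZ) * spec$we * spec$wi
  (num_e + num_i + num_ei) / denom
}

#' Small-weight cross-neuron voltage covariance and correlation
#'
#' Leading-order covariance of the stationary voltages of two symmetric
#' neurons, linear in each across-neuron spiking correlation:
#' \deqn{M_{12} \simeq \frac{\sum_{\alpha\beta} (V_\alpha - m)(V_\beta - m)
#'   \rho'_{\alpha\beta} K_\alpha K_\beta \sqrt{r_\alpha r_\beta}
#'   w_\alpha w_\beta}
#'   {2(1/\tau + \sum_\alpha K_\alpha r_\alpha w_\alpha)},}
#' over the denominator shared with [var_smallweight()].  The correlation is
#' `M12` divided by the variance under the full within-neuron specification.
#' Pure excitatory-inhibitory cross-correlation makes the covariance
#' negative.
#'
#' @param spec a [uniform_population_spec()].
#' @param m mean voltage override, mV.
#' @return List with `covariance` (mV^2), `correlation`, `variance` (mV^2)
#'   and `m` (mV).
#' @examples
#' sp <- uniform_population_spec(1000, 250, 0.001, 0.004, 1, 1,
#'                               rho_e = 0.02, rho_i = 0.02, rho_ei = 0.02,
#'                               rho_cross_ee = 0.013, rho_cross_ii = 0.013,
#'                               rho_cross_ei = 0.013)
#' cov_smallweight(sp)$correlation    # ~0.6 at 1 Hz
#' @export
cov_smallweight <- function(spec, m = NULL) {
  p <- spec$params
  if (is.null(m)) m <- smallweight_mean(spec)
  cc <- sw_rates(spec)
  denom <- 2 * (1 / p$tau + cc$ce + cc$ci)
  ee <- (p$Ve - m)^2 * spec$rho_cross_ee * spec$Ke^2 * spec$re * HZ * spec$we^2
  ii <- (p$Vi - m)^2 * spec$rho_cross_ii * spec$Ki^2 * spec$ri * HZ * spec$wi^2
  ei <- 2 * (p$Ve - m) * (p$Vi - m) * spec$rho_cross_ei *
    spec$Ke * spec$Ki * sqrt(spec$re * HZ * spec$ri * HZ) * spec$we * spec$wi
  covar <- (ee + ii + ei) / denom
  v <- var_smallweight(spec, m = m)
  list(covariance = covar, correlation = covar / v, variance = v, m = m)
}

#' Excitation share of the small-weight voltage variance
#'
#' `q = Ke re we^2 (Ve - m)^2 / sum_alpha K_alpha r_alpha w_alpha^2
#' (V_alpha - m)^2`: the fraction of the (asynchronous, current-like)
#' variance numerator contributed by excitation.  Decreasing in the mean
#' depolarization `m` when `Ve > |Vi|`.
#'
#' @param spec a [uniform_population_spec()].
#' @param m mean voltage, mV; defaults to [smallweight_mean()].
#' @return `q` in `[0, 1]`.
#' @examples
#' sp <- uniform_population_spec(1000, 250, 0.001, 0.004, 1, 1)
#' excitation_share_q(sp, m = 0)     # 0.9
#' @export
excitation_share_q <- function(spec, m = NULL) {
  p <- spec$params
  if (is.null(m)) m <- smallweight_mean(spec)
  e <- spec$Ke * spec$re * spec$we^2 * (p$Ve - m)^2
  i <- spec$Ki * spec$ri * spec$wi^2 * (p$Vi - m)^2
  if (e + i <= 0) stop("no variance: all pool terms are zero", call. = FALSE)
  e / (e + i)
}

#' Synchronous-to-asynchronous variance ratio kappa
#'
#' `kappa` is the ratio of the fully synchronous (`rho = 1`) to the
#' asynchronous (`rho = 0`) small-weight variance.  With independently
#' synchronous excitation and inhibition (case `"independent_EI"`),
#' `kappa = Ke q + Ki (1 - q)`; with jointly synchronous excitation and
#' inhibition (case `"correlated_EI"`), the synchronous hyperpolarizing and
#' depolarizing contributions interfere and
#' `kappa = (sqrt(Ke q) - sqrt(Ki (1 - q)))^2` (the sign follows from
#' `Vi - m < 0`).  Excitation alone gives `kappa = Ke`.
#'
#' @param spec a [uniform_population_spec()].
#' @param m mean voltage, mV; defaults to [smallweight_mean()].
#' @param case `"correlated_EI"` or `"independent_EI"`.
#' @return `kappa` (dimensionless, `>= 0`).
#' @examples
#' sp <- uniform_population_spec(1000, 250, 0.001, 0.004, 1, 1)
#' kappa_ratio(sp, m = 0) / 1000     # ~0.625
#' @export
kappa_ratio <- function(spec, m = NULL,
                        case = c("correlated_EI", "independent_EI")) {
  case <- match.arg(case)
  q <- excitation_share_q(spec, m)
  if (spec$Ki == 0 || q == 1) return(spec$Ke)
  if (case == "independent_EI")
    spec$Ke * q + spec$Ki * (1 - q)
  else
    (sqrt(spec$Ke * q) - sqrt(spec$Ki * (1 - q)))^2
}

#' Voltage correlation of two neurons from synchrony (saturating form)
#'
#' For two symmetric neurons with uniform within-neuron correlation `rho`
#' and across-neuron correlation `rho'`, the voltage correlation takes the
#' saturating form `rho_V = rho' / ((1 - rho)/kappa + rho)`, bounded above by
#' `rho'/rho`.  For small pools (`Ke << 1/rho`) it grows linearly as
#' `rho' * kappa`; for large pools it saturates at `rho'/rho`.
#'
#' @param rho_within uniform within-neuron pairwise spiking correlation.
#' @param rho_cross uniform across-neuron pairwise spiking correlation
#'   (`<= rho_within`).
#' @param kappa variance ratio from [kappa_ratio()].
#' @return The voltage correlation coefficient.
#' @examples
#' corr_synchrony(0.02, 0.013, kappa = 593)   # ~0.6
#' @export
corr_synchrony <- function(rho_within, rho_cross, kappa) {
  stopifnot(rho_within > 0, rho_cross >= 0, kappa >= 0)
  if (rho_cross > rho_within + 1e-12)
    stop("requires rho_cross <= rho_within", call. = FALSE)
  rho_cross / ((1 - rho_within) / kappa + rho_within)
}

#' Voltage correlation of two neurons sharing asynchronous inputs
#'
#' For symmetric neurons driven by independent inputs of which fractions
#' `fe` and `fi` are shared, `rho_V = fe q + fi (1 - q)` with `q` the
#' excitation share.  Excitation alone gives `rho_V = fe`.
#'
#' @param spec a [uniform_population_spec()] with `fe`, `fi` set.
#' @param m mean voltage, mV; defaults to [smallweight_mean()].
#' @return The voltage correlation coefficient.
#' @examples
#' sp <- uniform_population_spec(1000, 250, 0.001, 0.004, 1, 1,
#'                               fe = 0.85, fi = 0.4)
#' corr_shared_inputs(sp, m = 0)
#' @export
corr_shared_inputs <- function(spec, m = NULL) {
  q <- excitation_share_q(spec, m)
  spec$fe * q + spec$fi * (1 - q)
}

#' Approximate voltage skewness for excitatory drive
#'
#' Closed-form skewness of the stationary voltage of a neuron driven by
#' `Ke` excitatory inputs at rate `re` with pairwise correlation `rho_e`
#' (beta-binomial synchrony, `Ke we ~ 1` regime):
#' `S[V] ~ S_ref * (1 - 2 re tau)/(1 + re tau) * sqrt(1 + rho_e Ke)`,
#' where `S_ref = 2 sqrt(2) / (3 sqrt(Ke re tau))` is the skewness of the
#' matched asynchronous current-based model.  The drive factor changes sign
#' at `re = 1/(2 tau)`, giving a small negative skew at high rates.  This is
#' a coarser approximation than the third-moment display implemented in
#' [excitation_only_third_moment()]: its synchrony factor keeps only part of
#' the third-order correlation contribution, and it underestimates the exact
#' skewness under strong synchrony (see the package vignette).
#'
#' @param Ke number of excitatory inputs.
#' @param re input rate, Hz.
#' @param tau membrane time constant, ms.
#' @param rho_e pairwise spiking correlation.
#' @return List with `S_ref` (current-based reference skewness) and `S`
#'   (full approximation).
#' @examples
#' skewness_excitation(1000, 1, 15, 0.03)
#' @export
skewness_excitation <- function(Ke, re, tau = 15, rho_e = 0) {
  stopifnot(Ke >= 1, re > 0, tau > 0, rho_e >= 0, rho_e <= 1)
  x <- re * HZ * tau               # dimensionless drive r_e * tau
  S_ref <- 2 * sqrt(2) / (3 * sqrt(Ke * x))
  list(S_ref = S_ref,
       S = S_ref * (1 - 2 * x) / (1 + x) * sqrt(1 + rho_e * Ke))
}

#' Small-weight third central moment for excitatory drive
#'
#' Leading-order third centered moment of the stationary voltage under
#' uniform excitatory drive with pairwise correlation `rho_e` and
#' third-order correlation `rho_e3` (beta-binomial link
#' `rho_e3 = 2 rho_e^2 / (1 + rho_e)` by default):
#' \deqn{\frac{M_3}{(V_e - m)^3} = \frac{K_e r_e w_e^3
#'   \big[(\rho_{e,3}(K_e-2) + 3\rho_e)(K_e-1) + 1\big]}
#'   {3(1/\tau + K_e r_e w_e)} -
#'   \frac{\big[K_e r_e w_e^2 (1 + \rho_e (K_e - 1))\big]^2}
#'   {(1/\tau + K_e r_e w_e)^2}.}
#'
#' @param Ke pool size.
#' @param re input rate, Hz.
#' @param we dimensionless weight.
#' @param tau membrane time constant, ms.
#' @param rho_e pairwise spiking correlation.
#' @param rho_e3 third-order correlation (defaults to the beta-binomial
#'   value).
#' @param m mean voltage, mV (defaults to the self-consistent small-weight
#'   mean).
#' @param params a [neuron_params()].
#' @return `M3` in mV^3.
#' @examples
#' excitation_only_third_moment(1000, 1, 0.001)
#' @export
excitation_only_third_moment <- function(Ke, re, we, tau = 15, rho_e = 0,
                                         rho_e3 = 2 * rho_e^2 / (1 + rho_e),
                                         m = NULL, params = neuron_params(tau = tau)) {
  stopifnot(Ke >= 1, re >= 0, we >= 0)
  r <- re * HZ
  if (is.null(m)) {
    ce <- Ke * r * we
    m <- ce * params$Ve / (1 / tau + ce)
  }
  D <- 1 / tau + Ke * r * we
  bW3 <- Ke * r * we^3 * ((rho_e3 * (Ke - 2) + 3 * rho_e) * (Ke - 1) + 1)
  bW2 <- Ke * r * we^2 * (1 + rho_e * (Ke - 1))
  (params$Ve - m)^3 * (bW3 / (3 * D) - bW2^2 / D^2)
}

#' Invariance of small-weight statistics under count-compensated failure
#'
#' Checks the faulty-transmission scaling: thinning with success probability
#' `p` maps `(K, r, rho) -> (K, p r, p rho)`; compensating by input counts
#' (`K' = K/p`, weights unchanged) leaves the small-weight mean, variance
#' and skewness unchanged, whereas compensating by weights (`w' = w/p`)
#' inflates the asynchronous variance term by `1/p`.
#'
#' @param spec a [uniform_population_spec()].
#' @param p success probability in `(0, 1]`.
#' @return Data frame with the mean, variance and excitation-only skewness
#'   of the original, count-compensated and weight-compensated populations.
#'   Count compensation is applied on the continuous formulas (no rounding).
#' @examples
#' sp <- uniform_population_spec(1000, 250, 0.001, 0.004, 10, 10,
#'                               rho_e = 0.03, rho_i = 0.03)
#' faulty_scaling_check(sp, 0.1)
#' @export
faulty_scaling_check <- function(spec, p) {
  if (p <= 0) stop("p = 0 is degenerate", call. = FALSE)
  stopifnot(p <= 1)
  rescale <- function(spec, Kfac, wfac, rfac, rhofac) {
    s <- spec
    s$Ke <- s$Ke * Kfac; s$Ki <- s$Ki * Kfac
    s$we <- s$we * wfac; s$wi <- s$wi * wfac
    s$re <- s$re * rfac; s$ri <- s$ri * rfac
    for (nm in grep("^rho", names(s), value = TRUE)) s[[nm]] <- s[[nm]] * rhofac
    s
  }
  variants <- list(
    original = spec,
    count_compensated = rescale(spec, 1 / p, 1, p, p),
    weight_compensated = rescale(spec, 1, 1 / p, p, p))
  rows <- lapply(names(variants), function(nm) {
    s <- variants[[nm]]
    m <- smallweight_mean(s)
    v <- var_smallweight(s, m = m)
    sk <- NA_real_
    if (s$Ke > 0 && s$re > 0) {
      se <- s; se$Ki <- 0     # excitation-only skewness from the M3 display
      me <- smallweight_mean(se)
      ve <- var_smallweight(se, m = me)
      M3 <- excitation_only_third_moment(se$Ke, se$re, se$we, s$params$tau,
                                         se$rho_e, m = me, params = s$params)
      sk <- M3 / ve^1.5
    }
    data.frame(variant = nm, mean_mV = m, variance_mV2 = v,
               skewness_excitation = sk)
  })
  do.call(rbind, rows)
}
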