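## Independent oracles used across the suite.  These re-derive quantities by
## brute force (enumeration, closed-form algebra, factorial moments of the
## count law) without touching the code paths they check.

## per-event spiking correlation of an exchangeable pool directly from its
## count pmf: rho_n = E[prod X] / (E[X])^(n/n) with
## E[prod X over n fixed members] = E[(c)_n] / (K)_n
pool_corr_oracle <- function(pmf, K, n) {
  k <- seq_len(K)
  falling <- function(x, n) {
    out <- rep(1, length(x))
    for (j in 0:(n - 1)) out <- out * (x - j)
    pmax(out, 0)
  }
  E_prod <- sum(pmf * falling(k, n)) / falling(K, n)
  E_one <- sum(pmf * k) / K
  E_prod / E_one
}

## per-event pairwise correlation from a full pattern law (Eq-4 style)
pattern_corr_oracle <- function(patterns, prob, idx) {
  n <- length(idx)
  E_prod <- sum(prob * apply(patterns[, idx, drop = FALSE], 1, prod))
  marg <- colSums(prob * patterns[, idx, drop = FALSE])
  E_prod / prod(marg)^(1 / n)
}

## brute-force collective event rate of an exchangeable pool: b = r K / E[c]
pool_rate_oracle <- function(K, rate_hz, pmf) {
  rate_hz * K / sum(seq_len(K) * pmf)
}

## closed-form piecewise solution of the Marcus dynamics for a given drive
## (single neuron), evaluated at arbitrary times
closed_form_voltage <- function(times, ev_t, we, wi, p, v0 = p$rest) {
  vapply(times, function(t) {
    v <- v0; t_prev <- 0
    for (i in seq_along(ev_t)) {
      if (t < ev_t[i]) break
      v <- p$rest + (v - p$rest) * exp(-(ev_t[i] - t_prev) / p$tau)
      s <- we[i] + wi[i]
      v <- v + ((we[i] * p$Ve + wi[i] * p$Vi) / s - v) * (1 - exp(-s))
      t_prev <- ev_t[i]
    }
    p$rest + (v - p$rest) * exp(-(t - t_prev) / p$tau)
  }, 0)
}

## direct evaluation of the stationary mean and variance formulas for a
## single-neuron exchangeable excitatory/inhibitory count law given as atoms
## (independent of the package's triangular recursion)
palm_moments_oracle <- function(prob, We, Wi, b, p) {
  S <- We + Wi
  Y <- exp(-S)
  Rt <- ifelse(S > 0, (We * p$Ve + Wi * p$Vi) / ifelse(S > 0, S, 1), 0)
  m <- (b * sum(prob * Rt * (1 - Y)) + p$rest / p$tau) /
    (1 / p$tau + b * sum(prob * (1 - Y)))
  M2 <- b * sum(prob * (Rt - m)^2 * (1 - Y)^2) /
    (2 / p$tau + b * sum(prob * (1 - Y^2)))
  M3 <- (b * sum(prob * (Rt - m)^3 * (1 - Y)^3) +
           3 * M2 * b * sum(prob * (Rt - m) * (Y^2 - 1) * (1 - Y))) /
    (3 / p$tau + b * sum(prob * (1 - Y^3)))
  list(mean = m, variance = M2, M3 = M3)
}

## quick trace statistics for property checks (no bootstrap)
quick_stats <- function(trace, burn_in_ms = 300) {
  keep <- trace$time_ms >= burn_in_ms
  V <- trace$V[keep, , drop = FALSE]
  mu <- colMeans(V)
  ctr <- sweep(V, 2, mu)
  list(mean = mu, variance = colMeans(ctr^2),
       M3 = colMeans(ctr^3))
}
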