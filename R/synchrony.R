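## Synchrony models -----------------------------------------------------------
##
## A synchrony model is the jump law of the compound Poisson process driving a
## feedforward set of AONCB neurons.  It is represented as a mixture of
## *components*; at every synaptic event exactly one component generates the
## activation pattern.  Each component is built from *groups* of exchangeable
## inputs; a group fixes the pool type ("e" or "i"), the group size K and the
## (dimensionless) weight of each member onto every neuron.  Three pattern
## laws cover all constructions:
##
##   kind = "async"  one member active per event, chosen by rate;
##   kind = "sync"   all members active at every component event;
##   kind = "count"  a single group whose number of active members follows an
##                   explicit pmf over 1..K (beta-binomial or thinned laws),
##                   the active members drawn uniformly (exchangeability).
##
## All rates are stored internally in events/ms; the public interface accepts
## and reports Hz.

HZ <- 1e-3  # Hz -> events per ms

new_group <- function(pool, K, weights, rate = NULL, ids = NULL) {
  stopifnot(pool %in% c("e", "i"), K >= 1, all(weights >= 0))
  list(pool = pool, K = as.integer(K), weights = weights,
       rate = rate, ids = ids)
}

new_component <- function(kind, groups, rate = NULL, pmf = NULL, rho = NA_real_) {
  stopifnot(kind %in% c("async", "sync", "count"))
  if (kind == "count" && length(groups) != 1L)
    stop("'count' components must have a single group", call. = FALSE)
  structure(list(kind = kind, groups = groups, rate = rate,
                 pmf = pmf, rho = rho),
            class = "aoncb_component")
}

component_rate <- function(comp) {
  switch(comp$kind,
    async = sum(vapply(comp$groups, function(g) g$K * g$rate, 0)),
    sync  = comp$rate,
    count = {
      K <- comp$groups[[1]]$K
      comp$rate * K / sum(seq_len(K) * comp$pmf)
    })
}

## assign global input ids to groups lacking them
assign_ids <- function(components, start = 1L) {
  nxt <- start
  for (ci in seq_along(components)) {
    for (gi in seq_along(components[[ci]]$groups)) {
      g <- components[[ci]]$groups[[gi]]
      if (is.null(g$ids)) {
        components[[ci]]$groups[[gi]]$ids <- seq.int(nxt, length.out = g$K)
        nxt <- nxt + g$K
      }
    }
  }
  components
}

new_synchrony_model <- function(components, n_neurons, label = "synchrony model") {
  components <- assign_ids(components)
  m <- structure(list(components = components,
                      n_neurons = as.integer(n_neurons),
                      label = label),
                 class = "synchrony_model")
  m$input_table <- input_table(m)
  ## events must always activate something
  if (total_event_rate(m) < 0) stop("negative event rate", call. = FALSE)
  m
}

## one row per physical input: id, pool, total rate (per ms), weight matrix
input_table <- function(model) {
  ids <- integer(); pool <- character()
  rate <- numeric(); W <- NULL
  for (comp in model$components) {
    b_c <- component_rate(comp)
    for (g in comp$groups) {
      r_in <- switch(comp$kind, async = g$rate, sync = comp$rate,
                     count = comp$rate)
      new <- !(g$ids %in% ids)
      if (any(new)) {
        ids <- c(ids, g$ids[new])
        pool <- c(pool, rep(g$pool, sum(new)))
        rate <- c(rate, rep(0, sum(new)))
        W <- rbind(W, matrix(rep(g$weights, sum(new)), ncol = model$n_neurons,
                             byrow = TRUE))
      }
      rate[match(g$ids, ids)] <- rate[match(g$ids, ids)] + r_in
    }
  }
  o <- order(ids)
  list(id = ids[o], pool = pool[o], rate = rate[o],
       weights = W[o, , drop = FALSE])
}

#' @export
print.synchrony_model <- function(x, ...) {
  cat(sprintf("%s: %d input(s) onto %d neuron(s), %d component(s)\n",
              x$label, length(x$input_table$id), x$n_neurons,
              length(x$components)))
  cat(sprintf("  total synaptic-event rate b = %.6g Hz\n",
              total_event_rate(x) / HZ))
  invisible(x)
}

total_event_rate <- function(model) {
  sum(vapply(model$components, component_rate, 0))
}

## Beta-binomial pool ---------------------------------------------------------

#' Count distribution of the conditioned beta-binomial synchrony model
#'
#' Probability mass function of the number of coactive inputs per synaptic
#' event in a homogeneous pool of `K` exchangeable inputs with pairwise
#' spiking correlation `rho = 1/(1 + beta)`.  The law is the small-activation
#' limit of the beta-binomial distribution conditioned on a nonzero count:
#' `P[k]` proportional to `choose(K, k) * B(k, K - k + beta)` for
#' `k = 1, ..., K`, where `B` is the beta function.  Computed in log space so
#' that pools up to `K ~ 1e4` are handled without overflow.
#'
#' `beta = Inf` (equivalently `rho = 0`) encodes the asynchronous limit in
#' which every event has exactly one active input.
#'
#' @param K pool size (number of exchangeable inputs), `K >= 1`.
#' @param beta dispersion parameter `beta = 1/rho - 1 > 0`, or `Inf`.
#' @param rho alternative parameterization: pairwise spiking correlation in
#'   `[0, 1]`; supply exactly one of `beta`, `rho`.
#' @return Numeric vector of length `K`; `pmf[k]` is the probability that a
#'   synaptic event comprises exactly `k` coactive inputs.
#' @examples
#' betabinomial_count_pmf(5, rho = 0.03)
#' sum(betabinomial_count_pmf(100, rho = 0.25))
#' @export
betabinomial_count_pmf <- function(K, beta = NULL, rho = NULL) {
  if (is.null(beta) == is.null(rho))
    stop("supply exactly one of 'beta' or 'rho'", call. = FALSE)
  if (!is.null(rho)) {
    stopifnot(rho >= 0, rho <= 1)
    beta <- if (rho == 0) Inf else 1 / rho - 1
  }
  K <- as.integer(K)
  if (K < 1) stop("empty ensemble: K must be >= 1", call. = FALSE)
  if (K == 1L) return(1)
  if (is.infinite(beta)) return(c(1, rep(0, K - 1L)))
  if (beta <= 0) stop("dispersion beta must be > 0 (rho < 1)", call. = FALSE)
  k <- seq_len(K)
  lp <- lchoose(K, k) + lbeta(k, K - k + beta)
  p <- exp(lp - max(lp))
  p / sum(p)
}

#' Order-n spiking correlation of the beta-binomial pool
#'
#' Closed form for the order-`n` spiking correlation coefficient of the
#' homogeneous beta-binomial synchrony model:
#' `rho_(1..n) = prod_{k=1}^{n-1} k / (beta + k)` with `beta = 1/rho - 1`.
#' For `n = 2` this returns `rho` itself; for `n = 3` it equals
#' `2 rho^2 / (1 + rho)`.
#'
#' @param rho pairwise spiking correlation in `[0, 1]`.
#' @param n correlation order, `n >= 1`.
#' @return The order-`n` correlation coefficient.
#' @examples
#' betabinomial_correlation(0.03, 3)           # 2*0.03^2/1.03
#' @export
betabinomial_correlation <- function(rho, n) {
  stopifnot(rho >= 0, rho <= 1, n >= 1)
  if (n == 1) return(1)
  if (rho == 0) return(0)
  if (rho == 1) return(1)
  beta <- 1 / rho - 1
  k <- seq_len(n - 1)
  prod(k / (beta + k))
}

#' Collective synaptic-event rate of a beta-binomial pool
#'
#' The rate `b` of synaptic events (instants at which at least one input of
#' the pool activates) for `K` exchangeable inputs of individual rate `r` and
#' pairwise correlation `rho`: `b = r * beta * (digamma(K + beta) -
#' digamma(beta))`, which grows logarithmically in `K`.  Equivalently
#' `b = r * K / E[count]` under [betabinomial_count_pmf()].
#'
#' @param K pool size.
#' @param rate_hz per-input spike rate, Hz.
#' @param rho pairwise spiking correlation in `[0, 1]`.
#' @return Event rate in Hz.
#' @examples
#' betabinomial_event_rate(100, 1, 0.03)
#' betabinomial_event_rate(100, 1, 0)      # asynchronous: K * r
#' @export
betabinomial_event_rate <- function(K, rate_hz, rho) {
  stopifnot(K >= 1, rate_hz >= 0, rho >= 0, rho <= 1)
  if (rho == 0) return(K * rate_hz)
  if (rho == 1) return(rate_hz)
  beta <- 1 / rho - 1
  rate_hz * beta * (digamma(K + beta) - digamma(beta))
}

## Pool constructors ----------------------------------------------------------

pool_weights <- function(weight, neurons, n_neurons) {
  w <- numeric(n_neurons)
  w[neurons] <- weight
  w
}

#' Beta-binomial pool of synchronously correlated inputs
#'
#' A homogeneous pool of `K` exchangeable synaptic inputs with per-input rate
#' `rate_hz`, uniform pairwise spiking correlation `rho` and uniform weight
#' `weight` onto each neuron in `neurons` (a pool listed for several neurons
#' is *shared*: each member input innervates all of them).  `rho = 0` yields
#' independent inputs (represented explicitly, not as a numerical limit) and
#' `rho = 1` a fully synchronous pool.
#'
#' @param K pool size, `K >= 1`.
#' @param rate_hz per-input spike rate, Hz.
#' @param rho pairwise spiking correlation in `[0, 1]`.
#' @param pool `"e"` (excitatory) or `"i"` (inhibitory).
#' @param weight dimensionless synaptic weight of each member input.
#' @param neurons indices of the driven neurons.
#' @param n_neurons total number of neurons modeled (defaults to
#'   `max(neurons)`).
#' @return A `"synchrony_model"`.
#' @examples
#' betabinomial_pool(100, rate_hz = 1, rho = 0.03, weight = 0.01)
#' @export
betabinomial_pool <- function(K, rate_hz, rho, pool = "e", weight = 0.01,
                              neurons = 1L, n_neurons = max(neurons)) {
  stopifnot(rho >= 0, rho <= 1, rate_hz >= 0, weight >= 0)
  if (K < 1) stop("empty ensemble: K must be >= 1", call. = FALSE)
  w <- pool_weights(weight, neurons, n_neurons)
  r <- rate_hz * HZ
  comp <- if (rho == 0) {
    new_component("async", list(new_group(pool, K, w, rate = r)), rho = 0)
  } else if (rho == 1) {
    new_component("sync", list(new_group(pool, K, w)), rate = r, rho = 1)
  } else {
    new_component("count", list(new_group(pool, K, w)), rate = r,
                  pmf = betabinomial_count_pmf(K, rho = rho), rho = rho)
  }
  new_synchrony_model(list(comp), n_neurons,
                      label = sprintf("beta-binomial pool (K=%d, rho=%g)", K, rho))
}

#' @rdname betabinomial_pool
#' @export
independent_pool <- function(K, rate_hz, pool = "e", weight = 0.01,
                             neurons = 1L, n_neurons = max(neurons)) {
  m <- betabinomial_pool(K, rate_hz, 0, pool, weight, neurons, n_neurons)
  m$label <- sprintf("independent pool (K=%d)", K)
  m
}

#' @rdname betabinomial_pool
#' @export
synchronous_pool <- function(K, rate_hz, pool = "e", weight = 0.01,
                             neurons = 1L, n_neurons = max(neurons)) {
  m <- betabinomial_pool(K, rate_hz, 1, pool, weight, neurons, n_neurons)
  m$label <- sprintf("fully synchronous pool (K=%d)", K)
  m
}

#' Combine synchrony models into a mixture
#'
#' Concatenates the components of several models driving the same neuron set.
#' Input identities are kept distinct (ids are re-offset), so the combined
#' model describes the union of the inputs; total event rate is the sum of
#' the component rates.
#'
#' @param ... `"synchrony_model"` objects.
#' @param n_neurons number of neurons of the combined model (defaults to the
#'   maximum over the parts).
#' @param label optional label.
#' @return A `"synchrony_model"`.
#' @examples
#' m <- mixture_model(betabinomial_pool(10, 1, 0.1, "e", 0.01),
#'                    independent_pool(5, 2, "i", 0.04))
#' @export
mixture_model <- function(..., n_neurons = NULL, label = "mixture model") {
  parts <- list(...)
  if (length(parts) == 1L && is.list(parts[[1]]) &&
      !inherits(parts[[1]], "synchrony_model"))
    parts <- parts[[1]]
  stopifnot(length(parts) >= 1,
            all(vapply(parts, inherits, TRUE, "synchrony_model")))
  if (is.null(n_neurons))
    n_neurons <- max(vapply(parts, function(m) m$n_neurons, 0L))
  comps <- list(); offset <- 0L
  for (m in parts) {
    for (comp in m$components) {
      for (gi in seq_along(comp$groups)) {
        g <- comp$groups[[gi]]
        comp$groups[[gi]]$ids <- g$ids + offset
        w <- numeric(n_neurons); w[seq_along(g$weights)] <- g$weights
        comp$groups[[gi]]$weights <- w
      }
      comps <- c(comps, list(comp))
    }
    offset <- offset + max(unlist(lapply(m$components, function(cc)
      unlist(lapply(cc$groups, `[[`, "ids")))))
  }
  new_synchrony_model(comps, n_neurons, label)
}

## Standard single-neuron (or shared) excitatory/inhibitory drive ------------

#' Uniform excitatory/inhibitory synaptic drive with within-neuron synchrony
#'
#' Builds the jump law for a neuron receiving `Ke` excitatory and `Ki`
#' inhibitory inputs with uniform weights and rates, pool-specific pairwise
#' correlations `rho_e`, `rho_i` and a cross-pool correlation `rho_ei`
#' between excitatory and inhibitory inputs.  With `rho_ei = 0` the two pools
#' are independent beta-binomial pools.  With `rho_ei > 0` a fully
#' synchronous excitatory-inhibitory component of event rate
#' `rho_ei * sqrt(re * ri)` is mixed with residual beta-binomial pools whose
#' internal correlations are reduced so that all pairwise targets are met
#' exactly.
#'
#' @param Ke,Ki pool sizes (either may be 0).
#' @param re,ri per-input rates, Hz.
#' @param we,wi dimensionless weights.
#' @param rho_e,rho_i,rho_ei pairwise spiking correlations.
#' @param neurons indices of the driven neurons (several = shared drive).
#' @param n_neurons total number of neurons modeled.
#' @return A `"synchrony_model"`.
#' @examples
#' ensemble_model(Ke = 100, Ki = 25, re = 10, ri = 10,
#'                we = 0.01, wi = 0.04, rho_e = 0.03)
#' @export
ensemble_model <- function(Ke, Ki, re, ri, we, wi,
                           rho_e = 0, rho_i = 0, rho_ei = 0,
                           neurons = 1L, n_neurons = max(neurons)) {
  stopifnot(Ke >= 0, Ki >= 0, Ke + Ki >= 1)
  check_corr_targets(rho_e, rho_i, rho_ei)
  comps <- list()
  we_vec <- pool_weights(we, neurons, n_neurons)
  wi_vec <- pool_weights(wi, neurons, n_neurons)
  ids <- list(e = seq_len(Ke), i = Ke + seq_len(Ki))
  re_ms <- re * HZ; ri_ms <- ri * HZ
  b_ei <- if (rho_ei > 0) rho_ei * sqrt(re_ms * ri_ms) else 0
  if (b_ei > 0) {
    if (Ke == 0 || Ki == 0)
      stop("rho_ei > 0 requires both pools", call. = FALSE)
    comps <- c(comps, list(new_component("sync", list(
      new_group("e", Ke, we_vec, ids = ids$e),
      new_group("i", Ki, wi_vec, ids = ids$i)),
      rate = b_ei, rho = 1)))
  }
  add_pool <- function(comps, pool, K, r_ms, rho, w_vec) {
    if (K == 0 || r_ms <= b_ei) return(comps)
    r_res <- r_ms - b_ei
    rho_res <- (rho * r_ms - b_ei) / r_res
    if (rho_res < -1e-12)
      stop(sprintf("infeasible targets: rho_%s < rho_ei * sqrt(r_other/r_%s)",
                   pool, pool), call. = FALSE)
    rho_res <- max(rho_res, 0)
    pm <- betabinomial_pool(K, r_res / HZ, rho_res, pool, 1, neurons, n_neurons)
    comp <- pm$components[[1]]
    comp$groups[[1]]$weights <- w_vec
    comp$groups[[1]]$ids <- ids[[pool]]
    c(comps, list(comp))
  }
  comps <- add_pool(comps, "e", Ke, re_ms, rho_e, we_vec)
  comps <- add_pool(comps, "i", Ki, ri_ms, rho_i, wi_vec)
  new_synchrony_model(comps, n_neurons, label = "E/I ensemble")
}

check_corr_targets <- function(rho_e, rho_i, rho_ei) {
  stopifnot(rho_e >= 0, rho_e <= 1, rho_i >= 0, rho_i <= 1, rho_ei >= 0)
  if (rho_ei > sqrt(rho_e * rho_i) + 1e-12)
    stop("infeasible targets: rho_ei must not exceed sqrt(rho_e * rho_i)",
         call. = FALSE)
  invisible(TRUE)
}

## Calibrated two-neuron mixture ---------------------------------------------

#' Calibrate a mixture model to within- and across-neuron correlation targets
#'
#' Constructs the jump law for two symmetric neurons, each receiving its own
#' `Ke` excitatory and `Ki` inhibitory inputs with uniform weights and rates,
#' such that the induced pairwise spiking correlations match the requested
#' targets exactly: within-neuron `rho_e`, `rho_i`, `rho_ei` and
#' across-neuron `rho_cross_ee`, `rho_cross_ii`, `rho_cross_ei`.
#'
#' The construction mixes fully synchronous components (global across both
#' neurons, or neuron-private) with asynchronous remainders; the component
#' event rates are the unique solution of the linear system relating them to
#' the pairwise targets, and per-input marginal rates are preserved by
#' construction.  Targets outside the feasible cone of this construction
#' (which requires, e.g., `rho_cross_ei <= rho_ei` and
#' `rho_e >= rho_cross_ee + rho_ei - rho_cross_ei` for equal rates) raise an
#' error naming the violated constraint.
#'
#' @param targets named list or vector with elements `rho_e`, `rho_i`,
#'   `rho_ei`, `rho_cross_ee`, `rho_cross_ii`, `rho_cross_ei` (missing
#'   entries default to 0).
#' @param Ke,Ki per-neuron pool sizes.
#' @param re,ri per-input rates, Hz.
#' @param we,wi dimensionless weights.
#' @return A `"synchrony_model"` over two neurons, with attribute
#'   `"calibration"` reporting the targets, the induced coefficients (from
#'   [spiking_correlation()]) and the component rates.
#' @examples
#' m <- calibrate_mixture(list(rho_e = 0.04, rho_i = 0.04,
#'                             rho_cross_ee = 0.03, rho_cross_ii = 0.03),
#'                        Ke = 20, Ki = 5, re = 10, ri = 10,
#'                        we = 0.001, wi = 0.004)
#' attr(m, "calibration")$induced
#' @export
calibrate_mixture <- function(targets, Ke, Ki, re, ri, we, wi) {
  tg <- as.list(targets)
  g <- function(nm) if (!is.null(tg[[nm]])) tg[[nm]] else 0
  rho_e <- g("rho_e"); rho_i <- g("rho_i"); rho_ei <- g("rho_ei")
  pee <- g("rho_cross_ee"); pii <- g("rho_cross_ii"); pei <- g("rho_cross_ei")
  check_corr_targets(rho_e, rho_i, rho_ei)
  if (pee > rho_e + 1e-12 || pii > rho_i + 1e-12)
    stop("infeasible targets: cross-neuron correlation must not exceed the ",
         "within-neuron correlation (rho' <= rho)", call. = FALSE)
  re_ms <- re * HZ; ri_ms <- ri * HZ; rei <- sqrt(re_ms * ri_ms)
  ## component event rates (per ms), solved from the pairwise targets
  b <- c(EIg = pei * rei,
         Eg  = pee * re_ms - pei * rei,
         Ig  = pii * ri_ms - pei * rei,
         EI1 = (rho_ei - pei) * rei,
         E1  = rho_e * re_ms - pee * re_ms - (rho_ei - pei) * rei,
         I1  = rho_i * ri_ms - pii * ri_ms - (rho_ei - pei) * rei,
         Ae  = re_ms * (1 - rho_e),
         Ai  = ri_ms * (1 - rho_i))
  bad <- names(b)[b < -1e-12]
  if (length(bad)) {
    why <- c(EIg = "rho_cross_ei >= 0",
             Eg = "rho_cross_ee >= rho_cross_ei * sqrt(ri/re)",
             Ig = "rho_cross_ii >= rho_cross_ei * sqrt(re/ri)",
             EI1 = "rho_ei >= rho_cross_ei",
             E1 = "rho_e >= rho_cross_ee + (rho_ei - rho_cross_ei) * sqrt(ri/re)",
             I1 = "rho_i >= rho_cross_ii + (rho_ei - rho_cross_ei) * sqrt(re/ri)",
             Ae = "rho_e <= 1", Ai = "rho_i <= 1")
    stop("calibration infeasible for this mixture construction; violated: ",
         paste(why[bad], collapse = "; "), call. = FALSE)
  }
  b[b < 0] <- 0
  ## fixed input ids per neuron/pool so components overlap correctly
  idE <- list(seq_len(Ke), Ke + Ki + seq_len(Ke))
  idI <- list(Ke + seq_len(Ki), 2 * Ke + Ki + seq_len(Ki))
  gE <- function(a) new_group("e", Ke, pool_weights(we, a, 2), ids = idE[[a]])
  gI <- function(a) new_group("i", Ki, pool_weights(wi, a, 2), ids = idI[[a]])
  comps <- list()
  addc <- function(comps, rate, groups) {
    if (rate > 0) c(comps, list(new_component("sync", groups, rate = rate,
                                              rho = 1)))
    else comps
  }
  comps <- addc(comps, b[["EIg"]], list(gE(1), gI(1), gE(2), gI(2)))
  comps <- addc(comps, b[["Eg"]], list(gE(1), gE(2)))
  comps <- addc(comps, b[["Ig"]], list(gI(1), gI(2)))
  for (a in 1:2) {
    comps <- addc(comps, b[["EI1"]], list(gE(a), gI(a)))
    comps <- addc(comps, b[["E1"]], list(gE(a)))
    comps <- addc(comps, b[["I1"]], list(gI(a)))
    async_groups <- list()
    if (b[["Ae"]] > 0) {
      ga <- gE(a); ga$rate <- b[["Ae"]]
      async_groups <- c(async_groups, list(ga))
    }
    if (b[["Ai"]] > 0) {
      gi_ <- gI(a); gi_$rate <- b[["Ai"]]
      async_groups <- c(async_groups, list(gi_))
    }
    if (length(async_groups))
      comps <- c(comps, list(new_component("async", async_groups, rho = 0)))
  }
  m <- new_synchrony_model(comps, 2L, label = "calibrated two-neuron mixture")
  induced <- induced_pair_correlations(m, Ke, Ki)
  attr(m, "calibration") <- list(
    targets = list(rho_e = rho_e, rho_i = rho_i, rho_ei = rho_ei,
                   rho_cross_ee = pee, rho_cross_ii = pii, rho_cross_ei = pei),
    induced = induced, component_rates_hz = b / HZ)
  m
}

## class-level induced pairwise coefficients for the calibrated layout
induced_pair_correlations <- function(model, Ke, Ki) {
  pick <- function(pool, a) {
    it <- model$input_table
    ids <- it$id[it$pool == pool & it$weights[, a] > 0]
    ids[1:2]
  }
  sc <- function(ids) spiking_correlation(model, ids)
  out <- list()
  if (Ke >= 2) out$rho_e <- sc(pick("e", 1))
  if (Ki >= 2) out$rho_i <- sc(pick("i", 1))
  if (Ke >= 1 && Ki >= 1)
    out$rho_ei <- sc(c(pick("e", 1)[1], pick("i", 1)[1]))
  if (Ke >= 1) out$rho_cross_ee <- sc(c(pick("e", 1)[1], pick("e", 2)[1]))
  if (Ki >= 1) out$rho_cross_ii <- sc(c(pick("i", 1)[1], pick("i", 2)[1]))
  if (Ke >= 1 && Ki >= 1)
    out$rho_cross_ei <- sc(c(pick("e", 1)[1], pick("i", 2)[1]))
  out
}

#' Two neurons sharing a fraction of asynchronous inputs
#'
#' Builds the drive of two symmetric neurons receiving `Ke` excitatory and
#' `Ki` inhibitory independent (asynchronous) inputs each, of which fractions
#' `fe` and `fi` are common to both neurons.  Shared inputs innervate both
#' neurons with the same weight, so their pairwise spiking correlation across
#' neurons is 1 while all other pairs are uncorrelated.
#'
#' @param Ke,Ki per-neuron pool sizes.
#' @param re,ri per-input rates, Hz.
#' @param we,wi dimensionless weights.
#' @param fe,fi shared fractions in `[0, 1]` (rounded to whole inputs).
#' @return A `"synchrony_model"` over two neurons.
#' @examples
#' shared_input_model(100, 25, 10, 10, 0.01, 0.04, fe = 0.85, fi = 0.4)
#' @export
shared_input_model <- function(Ke, Ki, re, ri, we, wi, fe = 0, fi = 0) {
  stopifnot(fe >= 0, fe <= 1, fi >= 0, fi <= 1)
  groups <- list()
  add <- function(groups, pool, K, w1, w2, r_ms) {
    if (K >= 1)
      c(groups, list(new_group(pool, K, c(w1, w2), rate = r_ms)))
    else groups
  }
  nshare_e <- round(fe * Ke); nshare_i <- round(fi * Ki)
  groups <- add(groups, "e", nshare_e, we, we, re * HZ)
  groups <- add(groups, "e", Ke - nshare_e, we, 0, re * HZ)
  groups <- add(groups, "e", Ke - nshare_e, 0, we, re * HZ)
  groups <- add(groups, "i", nshare_i, wi, wi, ri * HZ)
  groups <- add(groups, "i", Ki - nshare_i, wi, 0, ri * HZ)
  groups <- add(groups, "i", Ki - nshare_i, 0, wi, ri * HZ)
  new_synchrony_model(list(new_component("async", groups, rho = 0)), 2L,
                      label = sprintf("shared asynchronous inputs (fe=%g, fi=%g)",
                                      fe, fi))
}

## Rate calculus --------------------------------------------------------------

## probability that a component event activates >= 1 input with positive
## weight onto some neuron in `neurons`, or >= 1 input among `inputs` ids
component_touch_prob <- function(comp, neurons = NULL, inputs = NULL) {
  g_touch <- function(g) {
    if (!is.null(neurons)) any(g$weights[neurons] > 0)
    else any(g$ids %in% inputs)
  }
  hit <- vapply(comp$groups, g_touch, TRUE)
  switch(comp$kind,
    sync = as.numeric(any(hit)),
    async = {
      tot <- vapply(comp$groups, function(g) g$K * g$rate, 0)
      num <- 0
      for (j in seq_along(comp$groups)) {
        g <- comp$groups[[j]]
        if (!hit[j]) next
        num <- num + if (!is.null(neurons)) g$K * g$rate
                     else sum(g$ids %in% inputs) * g$rate
      }
      num / sum(tot)
    },
    count = {
      g <- comp$groups[[1]]
      if (!is.null(neurons)) return(as.numeric(any(g$weights[neurons] > 0)))
      m <- sum(g$ids %in% inputs)
      if (m == 0) return(0)
      K <- g$K; k <- seq_len(K)
      ## P[none of the m marked inputs active | count = k] is hypergeometric
      p_none <- exp(lchoose(K - m, k) - lchoose(K, k))
      p_none[k > K - m] <- 0
      1 - sum(comp$pmf * p_none)
    })
}

#' Synaptic-event rate seen by a neuron subset or input subset
#'
#' Rate (Hz) of the instants at which at least one input with positive weight
#' onto one of `neurons` -- or at least one of the inputs listed in `inputs`
#' -- activates.  Under synchrony the rate of a subset is obtained by
#' subsampling the full ensemble rate, so it is monotone:
#' `event_rate(m, A) <= event_rate(m, B)` whenever `A` is a subset of `B`.
#' With no subset given, the total event rate of the model is returned.
#' A singleton input subset recovers that input's spike rate.
#'
#' @param model a `"synchrony_model"`.
#' @param neurons neuron indices (optional).
#' @param inputs global input ids, see `model$input_table` (optional;
#'   exclusive with `neurons`).
#' @return Event rate in Hz.
#' @examples
#' m <- betabinomial_pool(100, 1, 0.03)
#' event_rate(m)                      # collective rate, sublinear in K
#' event_rate(m, inputs = 1)          # the per-input rate, 1 Hz
#' @export
event_rate <- function(model, neurons = NULL, inputs = NULL) {
  stopifnot(inherits(model, "synchrony_model"))
  if (!is.null(neurons) && !is.null(inputs))
    stop("give either 'neurons' or 'inputs', not both", call. = FALSE)
  if (is.null(neurons) && is.null(inputs))
    return(total_event_rate(model) / HZ)
  if (!is.null(neurons) && length(neurons) == 0)
    stop("empty neuron subset", call. = FALSE)
  if (!is.null(inputs) && length(inputs) == 0)
    stop("empty input subset", call. = FALSE)
  b <- 0
  for (comp in model$components)
    b <- b + component_rate(comp) * component_touch_prob(comp, neurons, inputs)
  b / HZ
}

#' Pair-specific event rate and coincidence probability
#'
#' For two driven neurons, the rate `b12` of events at which at least one of
#' them receives input, and the coincidence probability
#' `q12 = P[W1 > 0, W2 > 0 | W1 + W2 > 0]`.  They satisfy
#' `b12 = (b1 + b2) / (1 + q12)` and `max(b1, b2) <= b12 <= b1 + b2`.
#'
#' @param model a `"synchrony_model"` covering both neurons.
#' @param pair the two neuron indices.
#' @return List with `b12`, `q12`, `b1`, `b2` (rates in Hz).
#' @examples
#' m <- shared_input_model(10, 0, 10, 0, 0.01, 0, fe = 0.5)
#' pair_event_rate(m)
#' @export
pair_event_rate <- function(model, pair = c(1L, 2L)) {
  stopifnot(length(pair) == 2)
  b1 <- event_rate(model, neurons = pair[1])
  b2 <- event_rate(model, neurons = pair[2])
  b12 <- event_rate(model, neurons = pair)
  list(b12 = b12, q12 = (b1 + b2) / b12 - 1, b1 = b1, b2 = b2)
}

## Spiking correlations -------------------------------------------------------

#' Spiking correlation coefficient of a set of inputs
#'
#' The order-`n` per-event spiking correlation of the `n` distinct inputs
#' `inputs`: `rho = E[X_k1 ... X_kn] / (E[X_k1] ... E[X_kn])^(1/n)` where
#' `X_k` is the indicator that input `k` activates at a synaptic event.
#' Always in `[0, 1]`; order 1 returns 1; asynchronous inputs give 0 for
#' `n >= 2`, full synchrony gives 1.  Evaluated exactly from the mixture
#' components (exchangeable count laws admit closed-form factorial moments).
#'
#' @param model a `"synchrony_model"`.
#' @param inputs vector of `n >= 1` distinct global input ids.
#' @return The correlation coefficient.
#' @examples
#' m <- betabinomial_pool(50, 1, 0.03)
#' spiking_correlation(m, c(1, 2))        # = 0.03
#' spiking_correlation(m, c(1, 2, 3))     # = 2*0.03^2/1.03
#' @export
spiking_correlation <- function(model, inputs) {
  stopifnot(inherits(model, "synchrony_model"), length(inputs) >= 1)
  inputs <- unique(inputs)
  n <- length(inputs)
  it <- model$input_table
  idx <- match(inputs, it$id)
  if (anyNA(idx)) stop("unknown input id(s)", call. = FALSE)
  marg <- it$rate[idx]
  if (any(marg <= 0))
    stop("correlation undefined: input has zero marginal rate", call. = FALSE)
  if (n == 1) return(1)
  num <- 0
  for (comp in model$components) {
    b_c <- component_rate(comp)
    members <- unlist(lapply(comp$groups, `[[`, "ids"))
    if (!all(inputs %in% members)) next
    num <- num + switch(comp$kind,
      async = 0,  # distinct inputs never coactivate
      sync = comp$rate,
      count = {
        K <- comp$groups[[1]]$K
        k <- seq_len(K)
        b_c * sum(comp$pmf * exp(lchoose(k, n) - lchoose(K, n)))
      })
  }
  num / prod(marg)^(1 / n)
}

## enumerate the full activation-pattern law (small models only)

#' Exact activation-pattern law of a small synchrony model
#'
#' Enumerates every activation pattern a synaptic event can produce together
#' with its probability.  Only feasible for small models (guarded at 50000
#' patterns); intended for fixtures and enumeration cross-checks.
#'
#' @param model a `"synchrony_model"`.
#' @param max_patterns guard on the enumeration size.
#' @return A list with `patterns` (logical matrix, one column per input id in
#'   `model$input_table$id`) and `prob`.  The all-zero pattern never appears.
#' @examples
#' pattern_pmf(betabinomial_pool(3, 1, 0.2))$prob
#' @export
pattern_pmf <- function(model, max_patterns = 50000) {
  it <- model$input_table
  nin <- length(it$id)
  b <- total_event_rate(model)
  pat <- list(); pr <- numeric()
  add <- function(ids_active, p) {
    v <- it$id %in% ids_active
    pat[[length(pat) + 1L]] <<- v
    pr[length(pr) + 1L] <<- p
  }
  for (comp in model$components) {
    w_c <- component_rate(comp) / b
    members <- unlist(lapply(comp$groups, `[[`, "ids"))
    switch(comp$kind,
      async = {
        tot <- sum(vapply(comp$groups, function(g) g$K * g$rate, 0))
        for (g in comp$groups)
          for (id in g$ids) add(id, w_c * g$rate / tot)
      },
      sync = add(members, w_c),
      count = {
        K <- comp$groups[[1]]$K
        if (sum(choose(K, seq_len(K))) > max_patterns)
          stop("pattern space too large to enumerate", call. = FALSE)
        for (k in seq_len(K)) {
          if (comp$pmf[k] == 0) next
          sets <- utils::combn(members, k, simplify = FALSE)
          for (s in sets) add(s, w_c * comp$pmf[k] / length(sets))
        }
      })
    if (length(pat) > max_patterns)
      stop("pattern space too large to enumerate", call. = FALSE)
  }
  P <- do.call(rbind, pat)
  colnames(P) <- it$id
  ## merge duplicated patterns
  key <- apply(P, 1, paste, collapse = "")
  first <- !duplicated(key)
  prob <- as.numeric(tapply(pr, key, sum)[key[first]])
  list(patterns = P[first, , drop = FALSE], prob = prob)
}
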