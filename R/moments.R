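## Exact stationary moments via the PASTA fixed point -------------------------
##
## At stationarity, sampling the voltages just before a synaptic event is
## equivalent to sampling them at a typical time (Poisson arrivals see time
## averages).  Writing U_a = V_a - rest_a, one Marcus update plus an
## exponential waiting time between consecutive events turns this invariance
## into a triangular linear system for the shifted mixed moments
## mu_A = E[prod_{a in A} U_a] over multisets A of neuron indices:
##
##   (sum_{a in A} 1/tau_a + b (1 - E[prod_A Y_a])) mu_A =
##       b * sum_{B strictly inside A} c(A,B) E[prod_{A\B} P_a prod_B Y_a] mu_B
##
## with Y_a = exp(-(We_a + Wi_a)), P_a = (Rt_a - rest_a) (1 - Y_a),
## Rt_a the jump-weighted reversal potential, b the full-ensemble event rate
## and c(A,B) the multiset binomial coefficients.  Events that do not touch
## the queried neurons contribute Y_a = 1, (1 - Y_a) = 0, so the
## unconditional jump law can be used throughout; the system is solved in
## increasing multiset size.

## discrete per-event jump law of the full model: atoms (prob, We, Wi)
jump_atoms <- function(model) {
  stopifnot(inherits(model, "synchrony_model"))
  n <- model$n_neurons
  b <- total_event_rate(model)
  probs <- numeric(); WE <- NULL; WI <- NULL
  add <- function(p, we, wi) {
    probs <<- c(probs, p)
    WE <<- rbind(WE, we); WI <<- rbind(WI, wi)
  }
  for (comp in model$components) {
    w_c <- component_rate(comp) / b
    switch(comp$kind,
      async = {
        tot <- sum(vapply(comp$groups, function(g) g$K * g$rate, 0))
        for (g in comp$groups) {
          we <- if (g$pool == "e") g$weights else numeric(n)
          wi <- if (g$pool == "i") g$weights else numeric(n)
          add(w_c * g$K * g$rate / tot, we, wi)
        }
      },
      sync = {
        we <- numeric(n); wi <- numeric(n)
        for (g in comp$groups) {
          if (g$pool == "e") we <- we + g$K * g$weights
          else wi <- wi + g$K * g$weights
        }
        add(w_c, we, wi)
      },
      count = {
        g <- comp$groups[[1]]
        k <- seq_len(g$K)
        keep <- comp$pmf > 0
        W <- outer(k[keep], g$weights)
        if (g$pool == "e")
          add2 <- cbind(W, matrix(0, sum(keep), n))
        else
          add2 <- cbind(matrix(0, sum(keep), n), W)
        probs <- c(probs, w_c * comp$pmf[keep])
        WE <- rbind(WE, add2[, seq_len(n), drop = FALSE])
        WI <- rbind(WI, add2[, n + seq_len(n), drop = FALSE])
      })
  }
  ## merge identical atoms
  key <- apply(cbind(WE, WI), 1, paste, collapse = ",")
  first <- !duplicated(key)
  p <- as.numeric(tapply(probs, key, sum)[key[first]])
  list(prob = p, We = WE[first, , drop = FALSE], Wi = WI[first, , drop = FALSE],
       b = b)
}

## per-neuron atom functionals used by the fixed point
jump_functionals <- function(model, params) {
  at <- jump_atoms(model)
  n <- model$n_neurons
  pl <- as_params_list(params, n)
  Ve <- vapply(pl, `[[`, 0, "Ve"); Vi <- vapply(pl, `[[`, 0, "Vi")
  rest <- vapply(pl, `[[`, 0, "rest")
  S <- at$We + at$Wi
  Y <- exp(-S)
  Rt <- matrix(0, nrow(S), n)
  pos <- S > 0
  Rt[pos] <- (sweep(at$We, 2, Ve, `*`) + sweep(at$Wi, 2, Vi, `*`))[pos] / S[pos]
  P <- (Rt - matrix(rest, nrow(S), n, byrow = TRUE)) * (1 - Y)
  list(atoms = at, Y = Y, P = P, Rt = Rt, b = at$b, params = pl,
       tau = vapply(pl, `[[`, 0, "tau"), rest = rest)
}

## all count vectors j with 0 <= j <= counts
sub_counts <- function(counts) {
  grids <- lapply(counts, function(k) 0:k)
  as.matrix(do.call(expand.grid, grids))
}

solve_moment_system <- function(jf, counts) {
  ## counts: named integer vector over distinct neuron indices
  memo <- new.env(parent = emptyenv())
  neurons <- as.integer(names(counts))
  nd <- length(neurons)
  Yq <- jf$Y[, neurons, drop = FALSE]
  Pq <- jf$P[, neurons, drop = FALSE]
  pr <- jf$atoms$prob
  tau_q <- jf$tau[neurons]
  b <- jf$b
  mu <- function(j) {
    if (all(j == 0)) return(1)
    key <- paste(j, collapse = ",")
    if (!is.null(memo[[key]])) return(memo[[key]])
    ## E[prod Y^j] and the lower-order terms
    subs <- sub_counts(j)
    full <- nrow(subs)  # last row == j itself (expand.grid order: first varies fastest)
    EyJ <- sum(pr * apply(Yq, 1, function(y) prod(y^j)))
    denom <- sum(j / tau_q) + b * (1 - EyJ)
    num <- 0
    for (r in seq_len(nrow(subs))) {
      jb <- subs[r, ]
      if (all(jb == j)) next
      coef <- prod(choose(j, jb))
      term <- rep(1, nrow(Pq))
      for (d in seq_len(nd)) {
        if (j[d] - jb[d] > 0) term <- term * Pq[, d]^(j[d] - jb[d])
        if (jb[d] > 0) term <- term * Yq[, d]^jb[d]
      }
      num <- num + coef * sum(pr * term) * mu(jb)
    }
    val <- b * num / denom
    memo[[key]] <- val
    val
  }
  list(mu = mu, memo = memo)
}

normalize_query <- function(query) {
  query <- as.integer(query)
  tab <- table(query)
  counts <- as.integer(tab)
  names(counts) <- names(tab)
  counts
}

#' Exact stationary mixed voltage moment of a feedforward neuron set
#'
#' Solves the PASTA fixed-point triangular system for the stationary shifted
#' moments `mu_A = E[prod_a (V_a - rest_a)]` over all sub-multisets of the
#' query, and recenters them about the stationary means to obtain the
#' centered mixed moment `M_A = E[prod_a (V_a - m_a)]`.  The multiset `query`
#' lists neuron indices with repetition (e.g. `c(1, 1)` for the variance of
#' neuron 1, `c(1, 2)` for a covariance, `c(1, 1, 1)` for the third moment).
#'
#' Expectations over the jump law are evaluated by exact enumeration of the
#' model's discrete per-event atoms (the group-exchangeable representation
#' keeps the atom count at O(total pool size)).
#'
#' @param model a `"synchrony_model"`.
#' @param params a [neuron_params()] or list of them.
#' @param query multiset of neuron indices; `|query|` is the moment order.
#' @return A list of class `"moment_result"` with `shifted` (`mu_A`),
#'   `central` (`M_A`), `mean` (stationary means of the involved neurons),
#'   `order`, and `engine` diagnostics.
#' @examples
#' m <- betabinomial_pool(100, 1, 0.03, weight = 0.01)
#' stationary_moment(m, neuron_params(), c(1, 1))$central   # voltage variance
#' @export
stationary_moment <- function(model, params, query) {
  counts <- normalize_query(query)
  neurons <- as.integer(names(counts))
  if (any(neurons < 1 | neurons > model$n_neurons))
    stop("query refers to unconfigured neurons", call. = FALSE)
  if (total_event_rate(model) == 0) {
    pl <- as_params_list(params, model$n_neurons)
    rest <- vapply(pl[neurons], `[[`, 0, "rest")
    return(structure(list(shifted = 0, central = 0, mean = rest,
                          query = rep(neurons, counts), order = sum(counts),
                          engine = "enumeration", n_atoms = 0L),
                     class = "moment_result"))
  }
  jf <- jump_functionals(model, params)
  sys <- solve_moment_system(jf, counts)
  mu_A <- sys$mu(counts)
  ## first moments per distinct neuron
  mu1 <- vapply(seq_along(neurons), function(d) {
    j <- integer(length(neurons)); j[d] <- 1L
    sys$mu(j)
  }, 0)
  means <- jf$rest[neurons] + mu1
  ## central moment by binomial recentering:
  ## M = sum_{j <= counts} prod C(n_d, j_d) (-mu1_d)^(n_d - j_d) mu(j)
  subs <- sub_counts(counts)
  M <- 0
  for (r in seq_len(nrow(subs))) {
    jb <- subs[r, ]
    coef <- prod(choose(counts, jb) * (-mu1)^(counts - jb))
    M <- M + coef * sys$mu(jb)
  }
  structure(list(shifted = mu_A, central = M, mean = means,
                 query = rep(neurons, counts), order = sum(counts),
                 engine = "enumeration",
                 n_atoms = length(jf$atoms$prob)),
            class = "moment_result")
}

#' @export
print.moment_result <- function(x, ...) {
  cat(sprintf("stationary moment of order %d for neurons {%s}\n",
              x$order, paste(x$query, collapse = ", ")))
  cat(sprintf("  shifted mu = %.8g, central M = %.8g\n", x$shifted, x$central))
  invisible(x)
}

#' Stationary mean voltage and rate coefficients
#'
#' The exact stationary mean of each queried neuron,
#' `m = (c_e Ve + c_i Vi + rest/tau) / (1/tau + c_e + c_i)`, with the rate
#' coefficients `c_alpha = b E[(W_alpha / (We + Wi)) (1 - exp(-(We+Wi)))]`
#' evaluated over the jump law.  Under asynchronous input the coefficients
#' reduce to `sum_k r_k (1 - exp(-w_k))` and, for small weights, to the
#' classical efficacies `sum_k r_k w_k`.
#'
#' @param model a `"synchrony_model"`.
#' @param params a [neuron_params()] or list of them.
#' @param neurons neuron indices (default all).
#' @return A list with `mean` (mV), and matrices of rate coefficients `c_e`,
#'   `c_i` (per ms).
#' @examples
#' stationary_mean(independent_pool(1000, 1, "e", 0.001), neuron_params())
#' @export
stationary_mean <- function(model, params, neurons = seq_len(model$n_neurons)) {
  if (total_event_rate(model) == 0) {
    pl <- as_params_list(params, model$n_neurons)
    rest <- vapply(pl[neurons], `[[`, 0, "rest")
    return(list(mean = setNames(rest, neurons),
                c_e = rep(0, length(neurons)), c_i = rep(0, length(neurons))))
  }
  jf <- jump_functionals(model, params)
  pr <- jf$atoms$prob
  S <- jf$atoms$We + jf$atoms$Wi
  fac <- matrix(0, nrow(S), ncol(S))
  pos <- S > 0
  fac[pos] <- (1 - exp(-S[pos])) / S[pos]
  ce <- jf$b * colSums(pr * jf$atoms$We * fac)
  ci <- jf$b * colSums(pr * jf$atoms$Wi * fac)
  pl <- jf$params
  m <- vapply(neurons, function(a) {
    p <- pl[[a]]
    (ce[a] * p$Ve + ci[a] * p$Vi + p$rest / p$tau) / (1 / p$tau + ce[a] + ci[a])
  }, 0)
  list(mean = setNames(m, neurons), c_e = ce[neurons], c_i = ci[neurons])
}

#' Exact stationary voltage variance
#'
#' @param model a `"synchrony_model"`.
#' @param params a [neuron_params()] or list of them.
#' @param neuron neuron index.
#' @return Variance in mV^2.
#' @export
stationary_variance <- function(model, params, neuron = 1L) {
  stationary_moment(model, params, c(neuron, neuron))$central
}

#' Exact stationary voltage covariance and correlation of a neuron pair
#'
#' Solves the PASTA fixed point for the mixed second moment of the pair and
#' for both variances, and reports the Pearson correlation
#' `rho_V = M12 / sqrt(M11 M22)`.  Inputs to the two neurons that never
#' coactivate yield zero covariance.
#'
#' @param model a `"synchrony_model"` covering both neurons.
#' @param params a [neuron_params()] or list of them.
#' @param pair the two neuron indices.
#' @return List with `covariance`, `correlation`, `variance` (length 2),
#'   `mean` (length 2), and the pair event rate `b12` (Hz).
#' @examples
#' m <- shared_input_model(50, 0, 10, 0, 0.01, 0, fe = 0.5)
#' stationary_covariance(m, neuron_params())$correlation
#' @export
stationary_covariance <- function(model, params, pair = c(1L, 2L)) {
  stopifnot(length(pair) == 2, pair[1] != pair[2])
  mom12 <- stationary_moment(model, params, pair)
  v1 <- stationary_variance(model, params, pair[1])
  v2 <- stationary_variance(model, params, pair[2])
  per <- pair_event_rate(model, pair)
  list(covariance = mom12$central,
       correlation = mom12$central / sqrt(v1 * v2),
       variance = c(v1, v2), mean = mom12$mean, b12 = per$b12, q12 = per$q12)
}

#' Exact stationary third central moment and skewness
#'
#' Third centered moment of a neuron's stationary voltage from the PASTA
#' triangular system, and the skewness `S[V] = M3 / M2^(3/2)`.
#'
#' @param model a `"synchrony_model"`.
#' @param params a [neuron_params()] or list of them.
#' @param neuron neuron index.
#' @return List with `M3` (mV^3), `variance` (mV^2), `skewness`, `mean`.
#' @examples
#' m <- betabinomial_pool(100, 1, 0.03, weight = 0.01)
#' third_central_moment(m, neuron_params())$skewness
#' @export
third_central_moment <- function(model, params, neuron = 1L) {
  m3 <- stationary_moment(model, params, rep(neuron, 3))
  v <- stationary_variance(model, params, neuron)
  if (v <= 0)
    stop("skewness undefined: stationary variance is zero", call. = FALSE)
  list(M3 = m3$central, variance = v, skewness = m3$central / v^1.5,
       mean = m3$mean)
}

## compact single-neuron third-moment formula (independent route, used in
## validation): M3 = (E[R^3 (1-Y)^3] + 3 M2 E[R (Y^2-1)(1-Y)]) /
##                   (3/(b tau) + E[1 - Y^3]), R = Rt - m
third_moment_palm <- function(model, params, neuron = 1L) {
  jf <- jump_functionals(model, params)
  pr <- jf$atoms$prob
  Y <- jf$Y[, neuron]; Rt <- jf$Rt[, neuron]
  ## restrict to events touching the neuron (others have Y = 1 and drop out)
  m <- stationary_mean(model, params, neuron)$mean
  M2 <- stationary_variance(model, params, neuron)
  b <- jf$b
  R <- Rt - m
  num <- sum(pr * (R * (1 - Y))^3) + 3 * M2 * sum(pr * R * (Y^2 - 1) * (1 - Y))
  den <- 3 / (b * jf$tau[neuron]) + sum(pr * (1 - Y^3))
  num / den
}
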