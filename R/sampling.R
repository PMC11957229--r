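## Sampling from synchrony models --------------------------------------------

#' Event drive: synaptic-event times and per-neuron conductance jumps
#'
#' Container for a realized sequence of synaptic events.  `We` and `Wi` hold
#' the dimensionless excitatory and inhibitory conductance jumps of each
#' neuron at each event (rows = events).
#'
#' @param time_ms strictly increasing event times, ms.
#' @param We,Wi numeric matrices (events x neurons) of nonnegative jumps, or
#'   vectors for a single neuron.
#' @return An object of class `"event_drive"`.
#' @examples
#' event_drive(c(10, 25, 40), We = c(0.01, 0, 0.02), Wi = c(0, 0.04, 0))
#' @export
event_drive <- function(time_ms, We, Wi) {
  We <- as.matrix(We); Wi <- as.matrix(Wi)
  stopifnot(nrow(We) == length(time_ms), nrow(Wi) == length(time_ms),
            ncol(We) == ncol(Wi), all(We >= 0), all(Wi >= 0))
  if (length(time_ms) > 1 && any(diff(time_ms) <= 0))
    stop("event times must be strictly increasing", call. = FALSE)
  if (length(time_ms) && any(rowSums(We) + rowSums(Wi) == 0))
    stop("every event must activate at least one input", call. = FALSE)
  structure(list(time_ms = as.numeric(time_ms), We = We, Wi = Wi,
                 n_neurons = ncol(We)),
            class = "event_drive")
}

#' @export
print.event_drive <- function(x, ...) {
  cat(sprintf("event drive: %d events on %d neuron(s), span %.6g ms\n",
              length(x$time_ms), x$n_neurons,
              if (length(x$time_ms)) diff(range(x$time_ms)) else 0))
  invisible(x)
}

#' Sample the compound-Poisson event drive of a synchrony model
#'
#' Draws event times from a Poisson process at the model's collective event
#' rate and, independently at each event, a jump vector from the model's
#' per-event jump law.
#'
#' @param model a `"synchrony_model"`.
#' @param duration_ms length of the sampled window, ms.
#' @param seed integer seed (every stochastic operation takes one).
#' @return An `"event_drive"`.
#' @examples
#' sample_events(betabinomial_pool(10, 5, 0.1), duration_ms = 1000, seed = 1)
#' @export
sample_events <- function(model, duration_ms, seed) {
  stopifnot(inherits(model, "synchrony_model"), duration_ms > 0)
  set.seed(seed)
  b <- total_event_rate(model)
  n <- rpois(1L, b * duration_ms)
  if (n == 0)
    return(event_drive(numeric(0),
                       matrix(0, 0, model$n_neurons),
                       matrix(0, 0, model$n_neurons)))
  tt <- sort(runif(n, 0, duration_ms))
  ## the RNG has ~2^32 granularity, so exact ties occur in long records;
  ## break them with a strictly increasing sub-nanosecond offset
  if (anyDuplicated(tt))
    tt <- tt + seq_len(n) * 1e-9
  atoms <- jump_atoms(model)
  idx <- sample.int(length(atoms$prob), n, replace = TRUE, prob = atoms$prob)
  event_drive(tt, atoms$We[idx, , drop = FALSE], atoms$Wi[idx, , drop = FALSE])
}

#' Sample per-input spike trains from a synchrony model
#'
#' Draws the full pattern-level realization: each synaptic event activates a
#' set of individual inputs according to the component law, and every
#' activation is emitted as one spike.  The result carries the model's input
#' table as attribute `"input_table"` so that trains can be converted back
#' into an [event_drive()] or thinned/jittered.
#'
#' @param model a `"synchrony_model"`.
#' @param duration_ms window length, ms.
#' @param seed integer seed.
#' @param pad_ms extra margin simulated on both sides of the window (used by
#'   the jitter pipeline to avoid edge bias); spikes are reported in
#'   `[-pad_ms, duration_ms + pad_ms]`.
#' @return A data frame of class `"spike_trains"` with columns `time_ms`,
#'   `input_id`, `pool`.
#' @examples
#' head(sample_spike_trains(betabinomial_pool(5, 10, 0.2), 1000, seed = 2))
#' @export
sample_spike_trains <- function(model, duration_ms, seed, pad_ms = 0) {
  stopifnot(inherits(model, "synchrony_model"), duration_ms > 0, pad_ms >= 0)
  set.seed(seed)
  t0 <- -pad_ms; t1 <- duration_ms + pad_ms
  ev_times <- numeric(); ev_members <- list()
  for (comp in model$components) {
    b_c <- component_rate(comp)
    n <- rpois(1L, b_c * (t1 - t0))
    if (n == 0) next
    tt <- runif(n, t0, t1)
    members <- unlist(lapply(comp$groups, `[[`, "ids"))
    act <- switch(comp$kind,
      async = {
        rates <- unlist(lapply(comp$groups, function(g) rep(g$rate, g$K)))
        as.list(members[sample.int(length(members), n, replace = TRUE,
                                   prob = rates)])
      },
      sync = rep(list(members), n),
      count = {
        K <- comp$groups[[1]]$K
        counts <- sample.int(K, n, replace = TRUE, prob = comp$pmf)
        lapply(counts, function(k) members[sample.int(K, k)])
      })
    ev_times <- c(ev_times, tt)
    ev_members <- c(ev_members, act)
  }
  o <- order(ev_times)
  ev_times <- ev_times[o]; ev_members <- ev_members[o]
  ## distinct events must not share a time stamp (RNG granularity ~2^-32)
  if (anyDuplicated(ev_times))
    ev_times <- ev_times + seq_along(ev_times) * 1e-9
  counts <- lengths(ev_members)
  times <- rep(ev_times, times = counts)
  ids <- unlist(ev_members)
  o <- order(times, ids)
  out <- data.frame(time_ms = times[o], input_id = ids[o])
  it <- model$input_table
  out$pool <- it$pool[match(out$input_id, it$id)]
  structure(out, class = c("spike_trains", "data.frame"),
            input_table = it, duration_ms = duration_ms)
}

#' Build an event drive from spike trains
#'
#' Groups spikes with identical time stamps into synaptic events and sums
#' the per-neuron conductance jumps from the input weights.  Weights are
#' taken from the trains' attached input table, or from the uniform `we`,
#' `wi` arguments for externally supplied event lists.
#'
#' @param trains a `"spike_trains"` data frame (or any data frame with
#'   `time_ms`, `input_id`, `pool`).
#' @param we,wi uniform weights used when no input table is attached.
#' @param n_neurons number of neurons when no input table is attached.
#' @param window optional `c(t0, t1)`; spikes outside are dropped.
#' @return An `"event_drive"`.
#' @export
drive_from_trains <- function(trains, we = NULL, wi = NULL, n_neurons = 1L,
                              window = NULL) {
  it <- attr(trains, "input_table")
  if (!is.null(window))
    trains <- trains[trains$time_ms >= window[1] & trains$time_ms < window[2], ]
  if (nrow(trains) == 0)
    return(event_drive(numeric(0), matrix(0, 0, n_neurons),
                       matrix(0, 0, n_neurons)))
  if (!is.null(it)) {
    n_neurons <- ncol(it$weights)
    W <- it$weights[match(trains$input_id, it$id), , drop = FALSE]
    pool <- it$pool[match(trains$input_id, it$id)]
  } else {
    if (is.null(we) || is.null(wi))
      stop("supply 'we' and 'wi' for trains without an input table",
           call. = FALSE)
    pool <- trains$pool
    W <- matrix(ifelse(pool == "e", we, wi), nrow(trains), n_neurons)
  }
  f <- factor(trains$time_ms, levels = unique(sort(trains$time_ms)))
  We <- rowsum(W * (pool == "e"), f)
  Wi <- rowsum(W * (pool == "i"), f)
  event_drive(as.numeric(levels(f)), We, Wi)
}

## Jitter and binned correlations --------------------------------------------

#' Jitter spike times with independent Gaussian shifts
#'
#' Adds an independent centered Gaussian time shift of standard deviation
#' `sigma_ms` to every spike, turning instantaneous synchrony into temporally
#' dispersed synchrony.  `sigma_ms = 0` returns the trains unchanged.  With
#' `crop` set, spikes jittered outside the window are dropped (generate with
#' `pad_ms >= 6 * sigma_ms` in [sample_spike_trains()] to avoid edge bias);
#' otherwise all spikes are kept, so the per-input spike counts are
#' preserved.  Coincident post-jitter spikes are kept as distinct spikes.
#'
#' @param trains a `"spike_trains"` data frame.
#' @param sigma_ms jitter standard deviation, ms.
#' @param seed integer seed.
#' @param crop optional `c(t0, t1)` window to crop to after jittering.
#' @return Jittered `"spike_trains"`, re-sorted by time.
#' @examples
#' tr <- sample_spike_trains(synchronous_pool(3, 5), 1000, seed = 1, pad_ms = 300)
#' jt <- jitter_spikes(tr, sigma_ms = 50, seed = 2, crop = c(0, 1000))
#' @export
jitter_spikes <- function(trains, sigma_ms, seed = NULL, crop = NULL) {
  stopifnot(sigma_ms >= 0)
  if (sigma_ms == 0) return(trains)
  if (!is.null(seed)) set.seed(seed)
  trains$time_ms <- trains$time_ms + rnorm(nrow(trains), 0, sigma_ms)
  if (!is.null(crop))
    trains <- trains[trains$time_ms >= crop[1] & trains$time_ms < crop[2], ]
  o <- order(trains$time_ms, trains$input_id)
  out <- trains[o, ]
  rownames(out) <- NULL
  out
}

#' Binned spike-count correlation
#'
#' Empirical pairwise spiking correlation at timescale `delta_t_ms`: spike
#' counts of every input are collected in disjoint bins of width
#' `delta_t_ms` aligned to the record start, and the Pearson correlations of
#' the count vectors are averaged with equal weight over all distinct input
#' pairs.
#'
#' @param trains a `"spike_trains"` data frame.
#' @param delta_t_ms bin width, ms; must not exceed the record length.
#' @param duration_ms record length, ms (defaults to the trains' attribute).
#' @param inputs optional subset of input ids.
#' @return Mean pairwise correlation coefficient.
#' @export
binned_spiking_correlation <- function(trains, delta_t_ms, duration_ms = NULL,
                                       inputs = NULL) {
  stopifnot(delta_t_ms > 0)
  if (is.null(duration_ms)) duration_ms <- attr(trains, "duration_ms")
  if (is.null(duration_ms)) duration_ms <- max(trains$time_ms)
  if (delta_t_ms > duration_ms)
    stop("bin width exceeds the record length", call. = FALSE)
  tr <- trains[trains$time_ms >= 0 & trains$time_ms < duration_ms, ]
  if (!is.null(inputs)) tr <- tr[tr$input_id %in% inputs, ]
  ids <- sort(unique(tr$input_id))
  n_bins <- floor(duration_ms / delta_t_ms)
  tr <- tr[tr$time_ms < n_bins * delta_t_ms, ]
  bin <- floor(tr$time_ms / delta_t_ms)
  col <- match(tr$input_id, ids)
  counts <- matrix(tabulate(bin * length(ids) + col,
                            nbins = n_bins * length(ids)),
                   nrow = n_bins, byrow = TRUE)
  keep <- apply(counts, 2, sd) > 0
  counts <- counts[, keep, drop = FALSE]
  if (ncol(counts) < 2)
    stop("need at least two inputs with spikes", call. = FALSE)
  C <- cor(counts)
  mean(C[upper.tri(C)])
}

## Faulty synaptic transmission ----------------------------------------------

#' Apply all-or-none synaptic transmission failure
#'
#' Thins synaptic activations with per-activation success probability `p`
#' (independent Bernoulli failures).  The effective per-input rate becomes
#' `p * r` and the effective pairwise spiking correlation `p * rho` (more
#' generally `rho * sqrt(p_k * p_l)`).  Applied to spike trains, each spike
#' is kept independently with probability `p`; applied to a synchrony model
#' built from single-group pool components, the per-event count law is
#' transformed exactly (binomial thinning conditioned on a nonzero count).
#'
#' Compensation modes counteract the rate loss: `"weights"` rescales all
#' weights to `w/p`; `"counts"` rebuilds each pool with `K' = round(K / p)`
#' inputs at rate `p * r` and correlation `p * rho` (weights unchanged),
#' which preserves the small-weight mean, variance and skewness.
#'
#' @param x a `"spike_trains"` data frame or a `"synchrony_model"`.
#' @param p success probability in `(0, 1]`.
#' @param seed integer seed (trains method only).
#' @param compensate one of `"none"`, `"weights"`, `"counts"` (model method).
#' @return An object of the same class as `x`.
#' @examples
#' m <- betabinomial_pool(100, 10, 0.2)
#' event_rate(apply_faulty_transmission(m, 0.5), inputs = 1)   # 5 Hz
#' @export
apply_faulty_transmission <- function(x, p, seed = NULL,
                                      compensate = c("none", "weights", "counts")) {
  UseMethod("apply_faulty_transmission")
}

#' @export
apply_faulty_transmission.spike_trains <- function(x, p, seed = NULL,
    compensate = c("none", "weights", "counts")) {
  compensate <- match.arg(compensate)
  if (compensate != "none")
    stop("compensation applies to models, not to realized trains",
         call. = FALSE)
  stopifnot(p > 0, p <= 1)
  if (p == 1) return(x)
  if (!is.null(seed)) set.seed(seed)
  keep <- runif(nrow(x)) < p
  out <- x[keep, ]
  rownames(out) <- NULL
  out
}

#' @export
apply_faulty_transmission.synchrony_model <- function(x, p, seed = NULL,
    compensate = c("none", "weights", "counts")) {
  compensate <- match.arg(compensate)
  if (p <= 0) stop("p = 0 is degenerate: no transmission at all", call. = FALSE)
  stopifnot(p <= 1)
  if (p == 1) return(x)
  comps <- lapply(x$components, function(comp) {
    if (length(comp$groups) != 1L)
      stop("exact model thinning requires single-group pool components; ",
           "thin sampled trains instead", call. = FALSE)
    g <- comp$groups[[1]]
    K <- g$K
    if (compensate == "counts") {
      rho <- comp$rho
      if (is.na(rho))
        stop("count compensation needs a pool with a known rho", call. = FALSE)
      r_in <- switch(comp$kind, async = g$rate, comp$rate)
      m2 <- betabinomial_pool(max(1L, round(K / p)), p * r_in / HZ, p * rho,
                              g$pool, 1, which(g$weights > 0),
                              n_neurons = length(g$weights))
      comp2 <- m2$components[[1]]
      comp2$groups[[1]]$weights <- g$weights
      comp2$groups[[1]]$ids <- NULL
      return(comp2)
    }
    wfac <- if (compensate == "weights") 1 / p else 1
    g$weights <- g$weights * wfac
    if (comp$kind == "async") {
      g$rate <- g$rate * p
      return(new_component("async", list(g), rho = 0))
    }
    ## binomial thinning of the count law, conditioned on a nonzero count
    pmf0 <- switch(comp$kind,
                   sync = c(rep(0, K - 1L), 1),
                   count = comp$pmf)
    newpmf <- vapply(seq_len(K), function(j)
      sum(pmf0 * dbinom(j, size = seq_len(K), prob = p)), 0)
    p_zero <- sum(pmf0 * dbinom(0, size = seq_len(K), prob = p))
    if (1 - p_zero <= 0)
      stop("thinning removed all activity", call. = FALSE)
    newpmf <- newpmf / (1 - p_zero)
    if (K == 1L)
      return(new_component("async", list(new_group(g$pool, 1L, g$weights,
                                                   rate = comp$rate * p)),
                           rho = 0))
    new_component("count", list(g), rate = comp$rate * p, pmf = newpmf,
                  rho = NA_real_)
  })
  new_synchrony_model(comps, x$n_neurons,
                      label = paste0(x$label, sprintf(" (thinned p=%g)", p)))
}
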