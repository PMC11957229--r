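## Marcus dynamics ------------------------------------------------------------

#' Marcus-rule voltage jump
#'
#' The discontinuous voltage update of a shot-noise-driven AONCB neuron at a
#' synaptic event with dimensionless conductance jumps `(we, wi)`:
#' `J = ((we*Ve + wi*Vi)/(we + wi) - v) * (1 - exp(-(we + wi)))`.
#' The update drives the voltage toward the jump-weighted reversal potential
#' and never takes it outside `(Vi, Ve)`.  The empty event `we = wi = 0`
#' yields `J = 0`; the rule is continuous there (the vanishing total jump is
#' evaluated with `expm1`).
#'
#' @param v pre-event voltage(s), mV.
#' @param we,wi nonnegative dimensionless jumps (vectors recycle).
#' @param params a [neuron_params()].
#' @return Jump(s) in mV.
#' @examples
#' marcus_jump(0, we = 0.01, wi = 0, neuron_params())   # ~0.597 mV
#' @export
marcus_jump <- function(v, we, wi, params = neuron_params()) {
  if (any(we < 0) || any(wi < 0))
    stop("jump sizes must be nonnegative", call. = FALSE)
  s <- we + wi
  target <- ifelse(s > 0, (we * params$Ve + wi * params$Vi) / ifelse(s > 0, s, 1), 0)
  (target - v) * (-expm1(-s))
}

new_voltage_trace <- function(time_ms, V, events, params_list) {
  structure(list(time_ms = time_ms, V = V, events = events,
                 params = params_list),
            class = "voltage_trace")
}

#' @export
print.voltage_trace <- function(x, ...) {
  cat(sprintf("voltage trace: %d neuron(s), %d samples over %.6g ms, %d events\n",
              ncol(x$V), nrow(x$V),
              if (nrow(x$V)) diff(range(x$time_ms)) else 0,
              if (is.null(x$events)) 0L else length(x$events$time_ms)))
  invisible(x)
}

#' Exact event-driven simulation of AONCB neurons (instantaneous synapses)
#'
#' Integrates the Marcus jump dynamics exactly: between synaptic events each
#' neuron relaxes exponentially toward its resting potential with its own
#' membrane time constant, and at event times the voltage jumps according to
#' [marcus_jump()].  Given the event drive, the returned trace is exact to
#' machine precision.  The trace records the voltage on a uniform sample
#' grid plus the exact pre- and post-event voltages `V(T-)`, `V(T)` at every
#' event (the pre-event values are what the PASTA principle equates with
#' typical-time samples).
#'
#' @param params a [neuron_params()] or list of them (one per neuron).
#' @param drive an [event_drive()].
#' @param duration_ms simulated window `[0, duration_ms]`.
#' @param dt_ms sample-grid spacing, ms.
#' @param v0 initial voltage(s) at `t = 0`; defaults to rest.
#' @return A `"voltage_trace"`: sample times `time_ms`, voltage matrix `V`
#'   (samples x neurons), and `events` with `time_ms`, `V_pre`, `V_post`,
#'   `We`, `Wi`.
#' @examples
#' d <- event_drive(c(30, 60), We = c(0.02, 0.05), Wi = c(0, 0))
#' tr <- simulate_event_driven(neuron_params(), d, duration_ms = 100)
#' @export
simulate_event_driven <- function(params, drive, duration_ms,
                                  dt_ms = 1, v0 = NULL) {
  stopifnot(inherits(drive, "event_drive"), duration_ms > 0, dt_ms > 0)
  n <- drive$n_neurons
  pl <- as_params_list(params, n)
  tau <- vapply(pl, `[[`, 0, "tau")
  rest <- vapply(pl, `[[`, 0, "rest")
  Ve <- vapply(pl, `[[`, 0, "Ve")
  Vi <- vapply(pl, `[[`, 0, "Vi")
  keep <- drive$time_ms >= 0 & drive$time_ms <= duration_ms
  ev_t <- drive$time_ms[keep]
  We <- drive$We[keep, , drop = FALSE]
  Wi <- drive$Wi[keep, , drop = FALSE]
  n_ev <- length(ev_t)
  if (is.null(v0)) v0 <- rest
  v0 <- rep_len(v0, n)

  ## pass 1: exact voltage at events
  V_pre <- matrix(0, n_ev, n); V_post <- matrix(0, n_ev, n)
  v <- v0; t_prev <- 0
  S <- We + Wi
  Y <- exp(-S)
  Rt <- matrix(0, n_ev, n)
  pos <- S > 0
  Rt[pos] <- (sweep(We, 2, Ve, `*`) + sweep(Wi, 2, Vi, `*`))[pos] / S[pos]
  for (i in seq_len(n_ev)) {
    v <- rest + (v - rest) * exp(-(ev_t[i] - t_prev) / tau)
    V_pre[i, ] <- v
    v <- v + (Rt[i, ] - v) * (1 - Y[i, ])
    V_post[i, ] <- v
    t_prev <- ev_t[i]
  }

  ## pass 2: vectorized grid fill from the per-segment closed form
  grid <- seq(0, duration_ms, by = dt_ms)
  seg <- findInterval(grid, ev_t)            # grid time == event time -> post
  t_start <- c(0, ev_t)[seg + 1L]
  V_start <- rbind(v0, V_post)[seg + 1L, , drop = FALSE]
  decay <- exp(-outer(grid - t_start, 1 / tau))
  restM <- matrix(rest, length(grid), n, byrow = TRUE)
  V <- (V_start - restM) * decay + restM
  dimnames(V) <- NULL
  new_voltage_trace(grid, V,
                    events = list(time_ms = ev_t, V_pre = V_pre,
                                  V_post = V_post, We = We, Wi = Wi),
                    params_list = pl)
}

#' Simulate AONCB neurons with a finite synaptic timescale
#'
#' Integrates the all-or-none conductance dynamics for synapses of duration
#' `tau_s_ms`: each synaptic event switches its conductance contribution on
#' for `tau_s_ms`, after which it switches off (overlapping activations
#' stack).  Conductances are therefore piecewise constant between
#' activation/deactivation edges, and the voltage is advanced with the exact
#' exponential solution on each piece (an event-queue integrator; `dt_ms`
#' only sets the output sampling grid).  As `tau_s_ms -> 0` at fixed
#' dimensionless weights the trace statistics converge to those of
#' [simulate_event_driven()].
#'
#' @param params a [neuron_params()] or list of them.
#' @param drive an [event_drive()] (per-event dimensionless jumps).
#' @param tau_s_ms synaptic activation time, ms.
#' @param duration_ms simulated window.
#' @param dt_ms output sampling step, ms.
#' @param v0 initial voltage(s); defaults to rest.
#' @return A `"voltage_trace"`; `events` records the activation edges with
#'   pre-edge voltages.
#' @examples
#' d <- event_drive(50, We = 0.05, Wi = 0)
#' tr <- simulate_finite_tau_s(neuron_params(), d, tau_s_ms = 2,
#'                             duration_ms = 100)
#' @export
simulate_finite_tau_s <- function(params, drive, tau_s_ms, duration_ms,
                                  dt_ms = 1, v0 = NULL) {
  stopifnot(inherits(drive, "event_drive"), tau_s_ms > 0, duration_ms > 0)
  n <- drive$n_neurons
  pl <- as_params_list(params, n)
  tau <- vapply(pl, `[[`, 0, "tau")
  rest <- vapply(pl, `[[`, 0, "rest")
  Ve <- vapply(pl, `[[`, 0, "Ve")
  Vi <- vapply(pl, `[[`, 0, "Vi")
  keep <- drive$time_ms >= -tau_s_ms & drive$time_ms <= duration_ms
  ev_t <- drive$time_ms[keep]
  We <- drive$We[keep, , drop = FALSE]
  Wi <- drive$Wi[keep, , drop = FALSE]
  ## edge queue: +w at the event, -w at event + tau_s
  edge_t <- c(ev_t, ev_t + tau_s_ms)
  edge_We <- rbind(We, -We)
  edge_Wi <- rbind(Wi, -Wi)
  o <- order(edge_t)
  edge_t <- edge_t[o]; edge_We <- edge_We[o, , drop = FALSE]
  edge_Wi <- edge_Wi[o, , drop = FALSE]
  inside <- edge_t > 0 & edge_t <= duration_ms
  ## state at t = 0 includes edges from events at t <= 0
  AE0 <- colSums(edge_We[edge_t <= 0, , drop = FALSE])
  AI0 <- colSums(edge_Wi[edge_t <= 0, , drop = FALSE])
  edge_t <- edge_t[inside]
  edge_We <- edge_We[inside, , drop = FALSE]
  edge_Wi <- edge_Wi[inside, , drop = FALSE]
  n_edge <- length(edge_t)
  if (is.null(v0)) v0 <- rest
  v <- rep_len(v0, n)

  ## per interval: conductance state -> (lambda, V_inf); exact advance
  lam_s <- matrix(0, n_edge + 1L, n)
  Vinf_s <- matrix(0, n_edge + 1L, n)
  V_edge <- matrix(0, n_edge + 1L, n)  # voltage at interval start
  AE <- pmax(AE0, 0); AI <- pmax(AI0, 0)
  t_prev <- 0
  V_edge[1L, ] <- v
  state <- function(AE, AI) {
    lam <- 1 / tau + (AE + AI) / tau_s_ms
    Vinf <- (rest / tau + AE * Ve / tau_s_ms + AI * Vi / tau_s_ms) / lam
    list(lam = lam, Vinf = Vinf)
  }
  st <- state(AE, AI)
  lam_s[1L, ] <- st$lam; Vinf_s[1L, ] <- st$Vinf
  V_pre <- matrix(0, n_edge, n)
  for (i in seq_len(n_edge)) {
    dt_i <- edge_t[i] - t_prev
    v <- st$Vinf + (v - st$Vinf) * exp(-st$lam * dt_i)
    V_pre[i, ] <- v
    AE <- pmax(AE + edge_We[i, ], 0)
    AI <- pmax(AI + edge_Wi[i, ], 0)
    st <- state(AE, AI)
    lam_s[i + 1L, ] <- st$lam; Vinf_s[i + 1L, ] <- st$Vinf
    V_edge[i + 1L, ] <- v
    t_prev <- edge_t[i]
  }
  grid <- seq(0, duration_ms, by = dt_ms)
  seg <- findInterval(grid, edge_t) + 1L
  t_start <- c(0, edge_t)[seg]
  dtg <- grid - t_start
  V <- Vinf_s[seg, , drop = FALSE] +
    (V_edge[seg, , drop = FALSE] - Vinf_s[seg, , drop = FALSE]) *
    exp(-lam_s[seg, , drop = FALSE] * dtg)
  dimnames(V) <- NULL
  on_edge <- edge_We > 0 | edge_Wi > 0
  anchors <- rowSums(on_edge) > 0
  new_voltage_trace(grid, V,
                    events = list(time_ms = edge_t[anchors],
                                  V_pre = V_pre[anchors, , drop = FALSE]),
                    params_list = pl)
}
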