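#' Membrane and reversal-potential parameters for one neuron
#'
#' Defines the passive constants of an AONCB neuron.  Voltages are measured
#' relative to the leak reversal potential, which is fixed at `VL = 0`; the
#' inhibitory and excitatory reversal potentials must straddle it.  The
#' resting drive `rest = I/G` is the voltage toward which the neuron relaxes
#' between synaptic events.
#'
#' Defaults follow common cortical estimates: `tau = 15` ms, `Ve = 60` mV,
#' `Vi = -10` mV (relative to leak), `rest = 0`.
#'
#' @param tau membrane time constant, ms (`tau = C/G`).
#' @param Ve excitatory reversal potential, mV; must be `> 0`.
#' @param Vi inhibitory reversal potential, mV; must be `< 0`.
#' @param rest resting potential `I/G`, mV; must lie in `(Vi, Ve)`.
#' @return An object of class `"neuron_params"`.
#' @examples
#' neuron_params()
#' neuron_params(tau = 20, rest = 2)
#' @export
neuron_params <- function(tau = 15, Ve = 60, Vi = -10, rest = 0) {
  stopifnot(is.numeric(tau), length(tau) == 1L, tau > 0)
  if (!(Vi < 0 && 0 < Ve))
    stop("reversal potentials must satisfy Vi < VL = 0 < Ve", call. = FALSE)
  if (!(rest > Vi && rest < Ve))
    stop("resting potential must lie strictly inside (Vi, Ve)", call. = FALSE)
  structure(list(tau = tau, Ve = Ve, Vi = Vi, rest = rest),
            class = "neuron_params")
}

#' @export
print.neuron_params <- function(x, ...) {
  cat(sprintf(
    "AONCB neuron: tau = %g ms, Ve = %g mV, Vi = %g mV, rest = %g mV\n",
    x$tau, x$Ve, x$Vi, x$rest))
  invisible(x)
}

#' Dimensionless synaptic weight from physical conductance
#'
#' Converts a peak synaptic conductance into the dimensionless weight
#' `w = g * tau_s / C` used throughout the package.
#'
#' @param g_nS peak synaptic conductance, nS.
#' @param tau_s_ms synaptic activation time, ms.
#' @param C_pF membrane capacitance, pF.
#' @return Dimensionless synaptic weight(s).
#' @examples
#' synaptic_weight(g_nS = 1, tau_s_ms = 2, C_pF = 200)
#' @export
synaptic_weight <- function(g_nS, tau_s_ms, C_pF) {
  stopifnot(all(g_nS >= 0), tau_s_ms > 0, C_pF > 0)
  g_nS * tau_s_ms / C_pF
}

## normalize a params argument for an n-neuron population to a list of
## neuron_params, one per neuron
as_params_list <- function(params, n_neurons) {
  if (inherits(params, "neuron_params"))
    return(rep(list(params), n_neurons))
  if (is.list(params) && all(vapply(params, inherits, TRUE, "neuron_params"))) {
    if (length(params) == 1L) return(rep(params, n_neurons))
    if (length(params) != n_neurons)
      stop("need one neuron_params per neuron (got ", length(params),
           " for ", n_neurons, " neurons)", call. = FALSE)
    return(params)
  }
  stop("'params' must be a neuron_params object or a list of them",
       call. = FALSE)
}
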