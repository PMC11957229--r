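---
title: "Subthreshold moments of conductance-based neurons under synchronous input"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Subthreshold moments of conductance-based neurons under synchronous input}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aoncb)
```

## The model

An all-or-none-conductance-based (AONCB) neuron is a passive membrane

$$C \dot V = G(V_L - V) + G_e(t)(V_e - V) + G_i(t)(V_i - V) + I,$$

whose excitatory and inhibitory conductances switch *on* by a fixed amount
$g$ for a duration $\tau_s$ whenever a synapse activates, then off again —
synaptic responses are all-or-none rather than exponentially graded.  We work
relative to the leak reversal ($V_L = 0$) with $V_i < 0 < V_e$, membrane time
constant $\tau = C/G$, and dimensionless synaptic weights $w = g\tau_s/C$.
Defaults follow common cortical estimates: $\tau = 15$ ms, $V_e = 60$ mV,
$V_i = -10$ mV; "large" weights are $w_e = 0.01$, $w_i = 0.04$ (about a 0.5 mV
somatic deflection near rest) and "moderate" weights are ten times smaller,
$w_e = 0.001$, $w_i = 0.004$.  We use the moderate values wherever the large
ones would conflict with the $K_e \simeq 1000$ regime, as the standard figure
conditions do.

In the limit of instantaneous synapses ($\epsilon = \tau_s/\tau \to 0^+$ at
fixed $w$) the drive becomes a compound-Poisson shot noise: synaptic *events*
arrive as a Poisson process of rate $b$, and at each event the voltage jumps
by the Marcus rule

$$J = \left(\frac{w_e V_e + w_i V_i}{w_e + w_i} - V(T^-)\right)
      \left(1 - e^{-(w_e + w_i)}\right),$$

which drives $V$ toward the jump-weighted reversal potential and confines it
to $(V_i, V_e)$.  Between events each neuron relaxes exponentially toward its
rest $I/G$.  `simulate_event_driven()` implements this scheme exactly (to
machine precision given the event drive); `marcus_jump()` exposes the update.

**Synchrony** means that several synapses activate at *exactly* the same
event time.  All synchrony structure lives in the distribution of the binary
activation pattern drawn per event; its second- and higher-order structure is
summarized by per-event spiking correlations
$\rho_{kl} = \mathbb E[X_k X_l] / \sqrt{\mathbb E[X_k]\,\mathbb E[X_l]}$
(and the $n$-th-root analogue at order $n$).  Only nonnegative correlations
are representable — a structural limit of jump-process synchrony.  Temporal
structure (non-Poisson event times, rate fluctuations) is out of scope.

## Synchrony models

`betabinomial_pool(K, r, rho)` is the workhorse: $K$ exchangeable inputs
whose per-event active count follows the conditioned beta-binomial law
$P[k] \propto \binom{K}{k} B(k, K - k + \beta)$, $k \ge 1$, with a single
dispersion parameter $\beta = 1/\rho - 1$.  It induces pairwise correlation
exactly $\rho$, order-$n$ correlation $\prod_{j<n} j/(\beta+j)$, and a
collective event rate $r\beta(\psi(K+\beta) - \psi(\beta))$ that grows only
logarithmically in $K$ — synchrony makes event rates sub-additive.  $\rho = 0$
is represented structurally (one input per event), never as a numerical
$\beta \to \infty$ limit; the pmf is computed in log space so $K \sim 10^4$
poses no overflow problem.

For two neurons with prescribed within-neuron ($\rho_e$, $\rho_i$,
$\rho_{ei}$) and across-neuron ($\rho'$) correlations,
`calibrate_mixture()` composes fully synchronous components (global and
neuron-private) with asynchronous remainders; because every pairwise
coefficient is *linear* in the component rates, the calibration is a small
linear solve and the induced coefficients are exact.  Feasibility requires
the Cauchy–Schwarz bound $\rho_{ei} \le \sqrt{\rho_e \rho_i}$ plus the cone
conditions of the construction (e.g. $\rho' \le \rho$,
$\rho'_{ei} \le \rho_{ei}$); violated constraints are named in the error.

One caveat is deliberate and worth stating plainly: a fully synchronous
component concentrates all its synchrony into events where an *entire pool*
fires at once (jumps of size $Kw$).  The small-weight formulas below depend
on the pattern law only through its pairwise coefficients, so they cannot see
this; the exact engine can.  At the standard two-neuron condition
($K_e w_e = 1$) the exact voltage correlation of the calibrated mixture
therefore falls below the small-weight prediction (about 0.45 versus 0.60 at
1 Hz) — a measure of how much the correlation depends on synchrony
*microstructure* beyond pairwise statistics, not a numerical defect.  For
single-neuron statistics we use beta-binomial pools throughout, whose
microstructure matches the theory's intent.

`shared_input_model()` covers the complementary mechanism (two neurons
sharing a fraction of independent inputs), `jitter_spikes()` +
`binned_spiking_correlation()` map instantaneous synchrony to the
timescale-dependent count correlations $\rho(\Delta t)$ that experiments
report, and `apply_faulty_transmission()` implements Bernoulli synaptic
failure with its exact thinned count laws ($r' = pr$, $\rho' = p\rho$).

## The exact moment engine

Stationarity plus "Poisson arrivals see time averages" (PASTA) — the law of
the voltage just before an event equals its typical-time law — turns one
Marcus update plus one exponential waiting time into a fixed point for the
shifted mixed moments $\mu_A = \mathbb E\prod_{a \in A}(V_a - I_a/G_a)$ over
multisets $A$ of neuron indices:

$$\Big(\textstyle\sum_{a\in A} \tfrac1{\tau_a} + b\,(1 - \mathbb E\prod_A Y_a)\Big)\,\mu_A
  = b \sum_{B \subsetneq A} c(A,B)\;
    \mathbb E\Big[\prod_{A\setminus B} (\tilde R_a - I_a/G_a)(1 - Y_a) \prod_B Y_a\Big]\,\mu_B,$$

with $Y_a = e^{-(W_{e,a}+W_{i,a})}$, $\tilde R_a$ the jump-weighted reversal
potential ($\tilde R_a := 0$ on empty per-neuron jumps, harmless because it
multiplies $1 - Y_a = 0$), and $c(A,B)$ multiset binomial coefficients.  The
system is triangular in the multiset order, so any mixed moment follows by
recursion (`stationary_moment()`), with means, covariances and third moments
as specializations.  Using the *full-ensemble* rate $b$ with the
unconditional jump law is equivalent to per-subset rates $b_A$ with
conditioned laws — events that miss $A$ contribute $Y_a \equiv 1$ — which is
both simpler and safer, since under synchrony $b_A$ is never additive.

Expectations over the jump law are evaluated by exact enumeration: every
model is represented by group-exchangeable components, so the per-event law
has $O(\sum K)$ discrete atoms (a beta-binomial pool of $10^4$ inputs is
$10^4$ atoms, not $2^{10^4}$ patterns).  No Monte-Carlo expectation engine is
needed; results carry `engine = "enumeration"`.

Two numerical points.  First, $1 - e^{-s}$ is evaluated with `expm1`, keeping
the Marcus rule continuous at empty events.  Second, centered moments are
obtained from shifted ones by binomial recentering, which cancels
catastrophically when the mean is large and the centered moment nearly
vanishes (absolute error $\sim 10^{-10}$ from $10^4$-magnitude shifted
moments); the compact single-neuron third-moment formula (same fixed point,
pre-centered) is used as an independent cross-check in the tests with a
tolerance scaled by $\mathrm{Var}^{3/2}$.

## Small-weight theory

Taylor-expanding the exact formulas to leading order in $w$ yields
interpretable closed forms in rates and correlations only (the package warns
above $w = 0.05$).  The variance gains the synchrony multiplier
$1 + (K - 1)\rho$ per pool, minus a cross term
$2(V_e - m)(m - V_i)\rho_{ei} K_e K_i \sqrt{r_e r_i} w_e w_i$ — E/I synchrony
always *reduces* variability.  Correlation-weighted terms carry
$\sqrt{r_k r_l}$, the only normalization consistent with the uniform
(rate-linear) forms and with the closed correlation formula below; the
package uses it throughout.

Derived quantities: the excitation share
$q = K_e r_e w_e^2 (V_e - m)^2 / \sum_\alpha K_\alpha r_\alpha w_\alpha^2 (V_\alpha - m)^2$;
the synchronous-to-asynchronous variance ratio $\kappa$, equal to
$K_e q + K_i(1-q)$ for independently synchronous pools and to
$(\sqrt{K_e q} - \sqrt{K_i(1-q)})^2$ for jointly synchronous excitation and
inhibition — the *signed* square root form is forced by deriving $\kappa$ as
the exact $\rho = 1$ to $\rho = 0$ variance ratio (the hyperpolarizing
synchronous contribution interferes destructively since $V_i - m < 0$), and
it alone reproduces the reference values $\kappa \approx 0.6 K_e$ at rest and
$\approx 0.08 K_e$ at 15 mV; and the saturating pair correlation
$\rho_{V_1V_2} = \rho' / ((1-\rho)/\kappa + \rho) < \rho'/\rho$.
`cov_smallweight()` (generic route) and `corr_synchrony()` ($\kappa$ route)
agree to machine precision, a deliberate dual-route design.

For excitation alone the third moment has the closed display implemented in
`excitation_only_third_moment()`; the triple-sum combinatorics give the
coefficient $(\rho_{e,3}(K_e-2) + 3\rho_e)(K_e-1) + 1$ (note the 3 — one per
choice of the repeated index).  `skewness_excitation()` implements the
further approximation
$S \approx \bar S \,\frac{1 - 2 r_e \tau}{1 + r_e \tau}\sqrt{1 + \rho_e K_e}$,
$\bar S = \tfrac{2\sqrt2}{3\sqrt{K_e r_e \tau}}$, whose drive factor changes
sign at $r_e = 1/(2\tau) \approx 33$ Hz.  Two caveats we verified against the
exact engine and long Marcus simulations:

* the $\sqrt{1 + \rho_e K_e}$ factor keeps only part of the third-order
  correlation contribution ($K^2\rho_{e,3} \approx 2(K\rho_e)^2/(1+\rho_e)$,
  of which it retains $(K\rho_e)^2$), so under strong synchrony the closed
  form *underestimates* the skewness (1.30 versus 2.45 exact at $K_e = 1000$,
  $r_e = 1$ Hz, $\rho_e = 0.03$);
* "small weight" is an expansion around small *jumps*.  At fixed $K w$ the
  beta-binomial count fraction converges to a latent law with $O(1)$ mass on
  large jumps, so the small-weight error decreases in $w$ only down to a
  synchrony-dependent plateau (about 6% for the variance and 13% for the
  third moment at $\rho = 0.03$, $Kw = 1$); asynchronously the error is a
  clean $O(w)$.

Skewness itself is scale-invariant: shrinking all weights at fixed rates
drives the variance to zero but the skewness to its small-weight *limit*; it
vanishes only in the large-drive Gaussian regime $K r \tau \to \infty$.

Bernoulli synaptic failure with success probability $p$ maps
$(K, r, \rho) \mapsto (K, pr, p\rho)$; compensating by counts
($K' = K/p$, weights unchanged) preserves the small-weight mean exactly and
the variance and skewness to $O(\rho(1-p)/K)$ — the exact multiplier carries
$K - 1$, not $K$ (`faulty_scaling_check()` reports all three variants).

## Simulation, estimation, validation

`simulate_finite_tau_s()` integrates the finite-$\tau_s$ dynamics over the
queue of conductance on/off edges with the exact exponential solution on
each piece (conductances are piecewise constant, so no Euler step is needed;
`dt` only sets the output grid).  This removes time-step bias, so the
$\epsilon$-convergence of its stationary statistics toward the event-driven
scheme ($\tau_s \in \{2, 0.2, 0.02\}$ ms) isolates the synaptic timescale
itself.  Overlapping activations of one synapse stack — the all-or-none
shape sums, with no saturation rule.

`trace_statistics()` estimates means, variances, skewness and pair
correlations from post-burn-in samples (burn-in $\max(10\tau, 50/b)$; traces
must extend $100\tau$ beyond it), with moving-block bootstrap standard
errors (block length $10\tau$, the voltage autocorrelation scale).
`pasta_check()` compares the uniform-grid and pre-event voltage samples by
Kolmogorov–Smirnov distance (threshold 0.1): Poisson drives pass; a periodic
drive collapses the pre-event law to a point and fails — the intended
negative control.  Every stochastic operation takes an explicit seed, and
identical seeds give bit-identical traces and sweep tables.  One
implementation detail: R's uniform RNG has $2^{-32}$ granularity, so long
records can produce exactly tied event times; samplers break such ties with
a strictly increasing sub-nanosecond offset, since simultaneity is reserved
for modeled synchrony.

## What the generator does and does not emulate

The synthetic drives realize the study conditions themselves: Poisson event
times, instantaneous synchrony with prescribed correlations, stationary
rates.  Real cortical input additionally shows temporally structured
synchrony (jitter at tens of milliseconds, rate waxing and waning),
negative correlations, and non-stationarity.  The jitter pipeline covers the
first of these (50 ms jitter of $\rho = 0.25$ trains reproduces the
$\rho(25\,\mathrm{ms}) \approx 0.03$ operating point); the others are out of
scope, so passing tests certify the mathematics of the stationary
jump-process model, not those further features of in-vivo data.

## Problem sizes

The test suite and acceptance script run at desk scale by choice: simulated
records of 100–500 s (versus hours for figure-quality Monte Carlo),
pools of $10^2$–$10^3$ inputs for simulation and up to $10^4$ for closed-form
checks, 100 jittered inputs over 500 s for the count-correlation condition,
and stochastic comparisons framed as 3-standard-error bands with
block-bootstrap SEs.  `run_experiment(..., scale = "full")` lengthens runs
tenfold for tighter bands.

## Known limitations

Only nonnegative spiking correlations; Poisson event times (no refractory or
oscillatory structure); subthreshold only — no spike generation or reset;
feedforward only — no recurrence; the calibrated two-neuron mixture matches
pairwise targets exactly but concentrates higher-order synchrony (see above);
and exact model-level thinning of faulty transmission is implemented for
single-group pool components (thin sampled trains for arbitrary models).
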