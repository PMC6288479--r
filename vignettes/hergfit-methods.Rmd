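---
title: "Model, inference machinery and design choices in hergfit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model, inference machinery and design choices in hergfit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hergfit)
```

# The model

hergfit simulates and fits a four-state Markov model of the rapid
delayed-rectifier potassium current IKr, carried by channels encoded by the
hERG gene. The observable is

$$ I_{Kr} = G_{Kr} \cdot O(V_m, t) \cdot (V_m - E_K), $$

where $O$ is the occupancy of the open state, $G_{Kr}$ the maximal
conductance (microsiemens; with voltage in mV the current comes out in nA)
and $E_K$ the potassium reversal potential. The gating states are open (O),
closed (C), inactivated-open (IO) and inactivated-closed (IC), with

$$
\begin{aligned}
d[O]/dt  &= k_O [C] + k_A [IO] - (k_C + k_I)[O],\\
d[C]/dt  &= k_C [O] + k_A [IC] - (k_O + k_I)[C],\\
d[IO]/dt &= k_I [O] + k_O [IC] - (k_A + k_C)[IO],\\
[IC]     &= 1 - ([O] + [C] + [IO]).
\end{aligned}
$$

Each transition rate is a two-parameter exponential function of voltage:
$k_O = k_{O1} e^{k_{O2} V}$, $k_C = k_{C1} e^{-k_{C2} V}$,
$k_I = k_{I1} e^{k_{I2} V}$, $k_A = k_{A1} e^{-k_{A2} V}$, giving nine free
scalars including $G_{Kr}$. Internally time is in ms, voltage in mV and
rates in ms$^{-1}$.

This topology factorises into two independent Hodgkin–Huxley gates — an
activation gate $a$ (C $\leftrightarrow$ O, rates $k_O$/$k_C$) and a
non-inactivation gate $r$ (rates $k_A$/$k_I$) — with $O = a\,r$. At constant
voltage each gate relaxes exponentially with
$a_\infty = k_O/(k_O+k_C)$, $\tau_a = 1/(k_O+k_C)$ (and analogously for
$r$). The package uses this closed form in two ways: as the analytic test
oracle for the numerical integrator, and to start every simulation from the
exact steady state at the protocol's initial holding voltage. Note the sign
convention ($k_{O2}, k_{I2} > 0$ act with $+V$; $k_{C2}, k_{A2} > 0$ with
$-V$) hard-wires the physiological orientation of both gates, so the two
gates are not interchangeable by relabelling parameters.

# Numerical integration

`simulateCurrent()` integrates the (O, C, IO) system with the stiff-capable
`lsoda` solver from deSolve, with the right-hand side compiled in C. IC is
eliminated by the conservation relation, so total occupancy is conserved
structurally rather than numerically. Integration restarts at every
protocol segment boundary: a voltage step is therefore seen by the solver
as a new initial-value problem, never smoothed over by step-size control.
Segments are left-closed/right-open, so a sample falling exactly on a
boundary takes the later segment's voltage.

Default tolerances are `rtol = 1e-8`, `atol = 1e-10`. These are tighter
than the 1e-6 accuracy the package promises against the analytic
constant-voltage solution because local step tolerances accumulate over a
multi-second protocol; with these defaults the observed global state error
stays below about 1e-8 across the reference prior box. Occupancies may
leave $[0,1]$ by no more than about the solver tolerance; outputs are
clamped to $[0,1]$ and an excursion beyond 1e-6 is treated as an
integration failure. Rate evaluation refuses exponent arguments beyond
±700 (double overflow) rather than clipping silently; during inference any
integration failure is mapped to a log-posterior of $-\infty$, i.e. a
rejected proposal.

# Protocols and the fixture protocol

Protocols are piecewise waveforms of hold, linear-ramp and sinusoid
segments, serialised as JSON. The built-in 12 s fixture protocol holds at
−80 mV for 2 s, applies a staircase of six 500 ms steps from −60 to
+40 mV each followed by a 500 ms step to −40 mV, then a 2 s sinusoidal
sweep (−30 ± 30 mV, 200 ms period) and a final 2 s hold at −80 mV. The
staircase probes activation and inactivation across the physiological
range, the −40 mV interludes produce the large resurgent tail currents
that expose recovery from inactivation and deactivation, and the sinusoid
adds continuously varying voltage information. The exact levels are a
design choice of this package (made once, for identifiability of all nine
parameters from a single trace); no published protocol is reproduced.

# Data files and the fitting specification

Experimental data enter as plain CSV whose first row names each variable;
the hERG case uses two equal-length columns of (time, current) pairs. The
fitting specification is a JSON document with entries `algorithm`,
`arguments`, `output`, `input` and `prior`. The `input` map tells the
simulator which data column supplies the sample times (outputs are
generated at exactly the times in the data file); the `output` map names
the data column compared against the model output `IKr`. Because binding
is name-based, reordering data columns — or renaming them together with
the maps — cannot change the bound problem.

Units must match the model's internal units, with one deliberate, narrow
exception: a time column declared in seconds (the convention of the data
files, which sample every 0.1 ms over a multi-second protocol) is
converted to milliseconds, and the conversion is logged. Nothing else is
converted; a current column not in nA is an error. Column units default to
seconds for time and nA for currents and can be declared explicitly in a
`units` sidecar entry of the specification. Flattened higher-dimensional
arrays are rejected rather than guessed at, and the reserved `objective`
entry must be `"gaussian"` if present.

Priors are box-uniform per parameter (`[lower, upper]`) or point
distributions (a single number). The reference document uses
Uniform(1e-7, 0.1) for the eight kinetic parameters, Uniform(0.0612,
0.612) for $G_{Kr}$, and fixes the observation-noise standard deviation
`obj:std` at 0.00463 (it may instead be given a uniform prior and
learned).

# The posterior

The likelihood is whole-trace Gaussian: observed currents are the
simulated trace plus i.i.d. $N(0, \sigma^2)$ noise, so
$\log L = -\tfrac{n}{2}\log(2\pi\sigma^2) - \sum_i r_i^2 / 2\sigma^2$.
The prior adds two kinds of zero-probability assertions on top of the
uniform box:

* **Physiological rate window.** For each of the four transition rates,
  its maximum over the voltage range $[-120, 60]$ mV (attained at an
  endpoint, since each rate is monotone in voltage) must lie within
  $[1.67\times 10^{-5}, 1000]$ ms$^{-1}$: the rate may neither explode
  anywhere in the range nor remain negligibly small across all of it.
  Applying the *lower* bound at the voltage where an exponential rate is
  *minimal* would instead exclude essentially every physiological
  parameterisation (a rate like $2.5\times10^{-4} e^{0.07 V}$ is
  vanishingly small at −120 mV by construction), which is why the window
  is applied to each rate's maximum — the convention of whole-trace hERG
  fitting studies. All bounds are configurable via `rateConstraint()`.

Off-support points short-circuit: the prior is evaluated first and a
$-\infty$ prior skips the ODE solve entirely.

# Optimisation and sampling

Inference runs in two stages, controlled by the specification's
`arguments`.

**CMA-ES seeding.** `cmaOpt` independent restarts of the Covariance Matrix
Adaptation Evolution Strategy minimise the negative log-posterior, each
with a budget of `cmaMaxFevals` objective evaluations (a
`budgetSplit = "total"` knob divides the budget across restarts instead;
per-restart is the default because each CMA-ES run on this posterior
needs a few thousand evaluations to traverse the narrow curved valleys of
the least-squares surface, and a split budget reliably stalls partway).
The best point found overall seeds the MCMC chain. The optimiser is the
standard $(\mu/\mu_w, \lambda)$-CMA-ES with cumulative step-size
adaptation and rank-one plus rank-$\mu$ covariance updates, including the
active (negative-weight) covariance update that speeds progress along
ill-conditioned valleys. Coordinates are rescaled to the unit box;
out-of-box proposals are evaluated at their projection with a quadratic
penalty.

Three further choices address structural features of this posterior, all
confined to the seeding search (the posterior itself is always evaluated
on the original scale and is never modified):

* the search runs in log-transformed coordinates — the prior spans six
  orders of magnitude for the kinetic prefactors, and a logarithmic scale
  is the natural geometry for rate constants;
* points violating the rate window, which have posterior density zero and
  would otherwise form a flat plateau the optimiser cannot sense, are
  ranked by a penalty growing with the magnitude of the violation;
* each restart first screens a batch of independent uniform draws from
  the prior box (5% of its budget, counted against it) and starts CMA-ES
  from the best draw with a modest initial step. Random parameter sets
  frequently describe a channel that carries almost no current under the
  protocol; on that "silent" plateau the residual surface is flat and a
  cold-started search tends to converge into it. Screening starts the
  search at a draw whose simulated current already resembles the data,
  with a modest initial step (0.15 of the transformed range) so the
  search refines that basin rather than leaping away from it.

**Adaptive-covariance MCMC.** A Metropolis chain of `numIters` iterations
with multivariate-normal proposals
$N(\theta,\ \eta_t\, s\, (\Sigma_t + 10^{-9} D))$, $s = 2.38^2/d$, where
$D$ is a fixed diagonal of squared per-coordinate scales. For an initial
phase of 200 iterations $\Sigma$ is a diagonal of (1% of each
coordinate's scale)$^2$; afterwards $\Sigma_t$ is the running empirical
covariance, updated every iteration with learning rate
$\gamma_t = (t - 200)^{-0.6}$, and the global scale $\eta_t$ is steered on
the log scale towards an acceptance rate of 0.25 (the acceptance-targeted
variant of Haario-style adaptive Metropolis). Two departures from the
plain fixed-scale Haario scheme matter for this posterior. First, the
scale targeting: under 12,001 data points the posterior is several orders
of magnitude narrower than the prior, and a fixed global scale would
spend most of the chain collapsing its proposal. Second, the
per-coordinate scales: each coordinate's characteristic scale is the
starting value's magnitude (floored at $10^{-4}$ of its prior range), not
the prior range itself — the kinetic prefactors sit at $10^{-5}$–$10^{-4}$
while the conductance sits at $10^{-1}$, and a range-proportional initial
proposal is rejected until the adapting covariance has collapsed, after
which the chain diffuses isotropically at the smallest parameter's scale
and never mixes within the budget. Sampling is on the untransformed
scale; out-of-support proposals are rejected and counted in the
acceptance rate. The first `burn` iterations are discarded; the full
retained chain is stored unthinned. One master seed drives everything:
sub-seeds for each CMA-ES restart and for the chain are derived from it
deterministically, and identical inputs plus seed reproduce the chain
bit-for-bit.

# Posterior summaries

`mapEstimate()` returns the maximum-posterior-density point over the
starting point and every retained iteration (ties to the earliest).
`credibleInterval()` uses equal-tailed empirical quantiles with linear
interpolation between order statistics (R's type-7 rule — stated because
no convention is universal). `marginalHistogram()` uses 50 equal-width
bins over the sample range by default, with a 3-bin moving average for
mode detection. The identifiability flags operationalise the usual
qualitative reading of marginals: *flat* if the 95% credible interval is
wider than 80% of the prior range, *multimodal* if more than one smoothed
local maximum exceeds 20% of the global maximum, where distinct maxima
must be separated by a valley dropping below half the smaller peak — the
histogram of a finite, autocorrelated chain always carries sampling
wiggle, which should not register as extra modes. Both thresholds are
heuristics, configurable, and reported alongside the raw histograms so
users can apply their own judgement. Convergence diagnostics beyond the
acceptance rate (R-hat, effective sample size) are deliberately out of
scope.

# Synthetic data

`generateDataset()` emulates a digitised whole-cell voltage-clamp
recording *after* pre-processing: the model trace on a regular grid (0.1
ms by default) plus i.i.d. Gaussian noise with standard deviation 0.00463
nA — the noise model the likelihood assumes. It deliberately omits leak
current, baseline drift, capacitance transients and series-resistance
artefacts of raw recordings; passing recovery tests on these fixtures
therefore demonstrates correctness of the inference machinery, not
robustness to the systematic errors of real data. Times are written in
seconds to match the data-file convention.

The default ground truth (`defaultTruth()`) is a fixed set of synthetic
constants in the physiological ballpark of published hERG kinetics at
room temperature — slow activation (hundreds of ms), fast inactivation
(tens of ms), $G_{Kr} = 0.15$ μS — chosen once so that the parameters lie
strictly inside the reference prior box, satisfy the rate window, and give
a trace signal-to-noise far above 20 under the reference noise level.
They are not estimates from any recorded cell.

# Scaled-down study sizes

The recovery study used by the test suite and the acceptance script runs
the fixture protocol at 1 ms sampling (12,001 points) with reduced
budgets — 2 CMA-ES restarts of 4000 evaluations each, 20,000 MCMC
iterations with 10,000 burn-in — rather than the reference configuration
(5 restarts of 20,000 evaluations; 100,000 iterations, 50,000 burn-in).
These sizes were chosen as the smallest at which the recovery properties
(credible-interval coverage of the truth, MAP-trace RMSE at the noise
floor, well-constrained unimodal marginals) hold reliably. The
identifiability contrast replaces the fixture protocol with a single
uninformative 12 s hold at −80 mV, under which the kinetic marginals
widen dramatically — the operational signature of an experiment that does
not constrain the model.

# Known limitations

* Only the built-in four-state hERG topology ships; there is no
  CellML/SBML ingestion, no temperature dependence and no drug-block term.
* Only whole-trace Gaussian likelihoods and box-uniform/point priors are
  supported; `objective` is reserved for future extension.
* Unit handling converts time only; all other mismatches are errors by
  design rather than silently translated.
* The sampler is a single adaptive chain; multimodal posteriors are
  flagged (via the marginal diagnostics) but not resolved by tempering or
  multiple chains.
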