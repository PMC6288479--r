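# hergfit

Bayesian fitting of a hERG channel Markov model to voltage-clamp current
recordings.

## The problem

The rapid delayed-rectifier potassium current IKr, carried by channels
encoded by the hERG gene, shapes cardiac repolarisation and is central to
drug-safety assessment. Quantitative models of IKr gating are fitted to
whole current traces recorded under voltage clamp, and a point estimate of
the parameters is not enough: experimentalists and modellers need to know
*how well* the data constrain each parameter, and whether the chosen
voltage protocol identifies the model at all.

hergfit is a toolkit for exactly this workflow, aimed at cardiac
electrophysiologists and modellers. It provides:

* a four-state Markov model of IKr (open, closed, inactivated-open,
  inactivated-closed) with compiled ODE simulation under arbitrary
  piecewise voltage-clamp protocols (holds, ramps, sinusoids);
* a machine-readable JSON *fitting specification* binding algorithm,
  arguments, data-to-model name maps and priors, plus a plain-CSV data
  format, so fitting experiments are reproducible and data files can be
  swapped without touching protocols;
* Bayesian inference of the nine model parameters: multi-start CMA-ES
  global optimisation to seed an adaptive-covariance Metropolis MCMC
  sampler under a whole-trace Gaussian likelihood, with box-uniform priors
  and physiological rate-window assertions;
* posterior summaries in the style of fitting studies: maximum posterior
  density (MAP) overlays, marginal histograms, credible intervals and
  per-parameter identifiability flags (flat / multimodal);
* a synthetic-data module generating fully self-contained fixtures with
  known ground truth, so every stage is testable without recordings.

## The model

$$ I_{Kr} = G_{Kr} \cdot O(V_m, t) \cdot (V_m - E_K) $$

with open-state occupancy $O$ governed by the four-state system

$$ d[O]/dt = k_O [C] + k_A [IO] - (k_C + k_I) [O], \quad \ldots \quad
   [IC] = 1 - [O] - [C] - [IO], $$

and voltage-dependent rates $k_O = k_{O1} e^{k_{O2} V}$,
$k_C = k_{C1} e^{-k_{C2} V}$, $k_I = k_{I1} e^{k_{I2} V}$,
$k_A = k_{A1} e^{-k_{A2} V}$ — nine free scalars including $G_{Kr}$. The
topology factorises into independent activation and inactivation gates,
which gives closed-form solutions at constant voltage, used throughout the
test suite as an analytic oracle for the integrator.

## Worked example

Generate a synthetic recording from the built-in ground truth, fit it, and
summarise the posterior:

```r
library(hergfit)

truth <- truthRecord(defaultTruth()@params, dt = 1)   # 1 ms sampling
ds    <- generateDataset(truth)
ds$data
#> DataTable: 12001 rows x 2 columns (t [s], exp_IKr [nA])

problem <- bindProblem(reducedFittingSpec(), ds$data,
                       protocol = truth@protocol)
problem
#> FittingProblem: 12001 samples over [0, 12000] ms
#>   9 free parameter(s): kO1, kO2, kC1, kC2, kI1, kI2, kA1, kA2, GKr
#>   noise sigma: fixed at 0.00463
#>   conversions: time column 't' converted from s to ms

fit <- runFitting(problem, seed = 1)   # a few minutes: ~28,000 ODE solves
fit$posterior
#> PosteriorSample: 10000 retained iterations, 9 parameter(s)
#>   acceptance rate 0.241, max log-posterior 47431.4254, seed 312928385

ov <- predictionOverlay(problem, fit$map)
attr(ov, "rmse")
#> [1] 0.004655552                        # the injected noise floor (0.00463)
credibleInterval(fit$posterior, "GKr", 0.95)
#> [1] 0.1492566 0.1507084                # brackets the true 0.15
marginalHistogram(fit$posterior, "kA1")
#> MarginalSummary for kA1: mean 0.00500286, sd 1.26e-05, 95% CI [0.00497897, 0.00502747]
#>   mode ~ 0.00500153; flags: multimodal = FALSE, flat = FALSE
identifiabilityFlags(fit$posterior)
```

The MAP-simulated trace overlays the data at the noise floor (RMSE close
to the injected sigma = 0.00463 nA), the 95% credible intervals bracket
the generating parameters, and all marginals are tightly unimodal — the
signature of a protocol that identifies the model. Rerunning the same
fit against data from a bare −80 mV hold instead produces kinetic
marginals orders of magnitude wider: that protocol carries almost no
information about gating.

Command-line wrappers live in `inst/cli/`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/synth.R", package="hergfit"))')" \
    --out fixture --dt 1
Rscript "$(Rscript -e 'cat(system.file("cli/fit.R", package="hergfit"))')" \
    --spec fixture/spec.json --data fixture/data.csv \
    --protocol fixture/protocol.json --seed 1 --out fit-output
```

## Package layout

* `R/`, `src/` — S4 classes, simulation (compiled RHS via deSolve),
  fitting IO, inference, posterior summaries, synthetic data.
* `inst/extdata/herg_fitting_spec.json` — the reference fitting document.
* `vignettes/hergfit-methods.Rmd` — the model, the inference machinery,
  and every tunable with units and defaults.
* `tests/testthat/` — unit, property and acceptance suites.
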