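---
title: "Emulation-based parameter inference for left-ventricle biomechanics: models, choices and limitations"
author: "lvemu authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Emulation-based parameter inference for left-ventricle biomechanics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lvemu)
```

## The inverse problem

Passive myocardium is modelled by the Holzapfel–Ogden (HO) strain-energy
function: an isotropic exponential in the first invariant $I_1$, tension-only
exponential terms in the fibre and sheet stretches $I_{4f}, I_{4s}$, a
fibre–sheet coupling term in $I_{8fs}$, and a quadratic volumetric penalty
$\tfrac{K}{2}(J-1)^2$ with $K = 10^6$. Its eight constants are strongly
correlated under in-vivo data, so the package works in the reduced
parameterization: four multipliers $\theta \in [0.1, 5]^4$ of published
reference values ($a_0 = 0.22$ kPa, $b_0 = 1.62$, $a_{f0} = 2.43$ kPa,
$a_{s0} = 0.56$ kPa, $b_{f0} = 1.83$, $b_{s0} = 0.77$, $a_{fs0} = 0.39$ kPa,
$b_{fs0} = 1.70$), with $\theta_1$ scaling the isotropic pair, $\theta_2$ the
anisotropic stiffnesses, $\theta_3$ the anisotropic exponents and $\theta_4$
the coupling pair. The data vector has 25 entries: 24 regional
circumferential strains and the end-diastolic volume.

Inference minimises a surrogate of the negative log-likelihood loss between
the (emulated) model output and the observation. Two loss metrics are
provided: the Euclidean loss $\tfrac{1}{2\sigma^2}\lVert \hat m(\theta) -
y_0\rVert^2$ and the Mahalanobis loss $\tfrac12 r^\top \Sigma^{-1} r$ with
$\Sigma$ the covariance of the training outputs, precomputed once and kept
fixed. Additive constants and the scale $\alpha$ of the likelihood are
dropped throughout — they do not move the minimiser — and $\sigma$ defaults
to 1, making the Euclidean loss half the sum of squared residuals.

## Emulation strategies

**Output emulation** fits 25 independent scalar emulators, one per output
column, over a Sobol space-filling design; the loss is then composed with
the emulated output vector. Everything can be trained before the
observation arrives. **Loss emulation** evaluates the chosen loss between
every training output and the observation and fits a single scalar emulator
to the resulting surface; it trains only after the data arrive but needs
one model instead of 25. Estimation minimises the GP predictive mean of the
emulated loss.

## Interpolators

### Local (K-nearest-neighbour) GP

For each query the K = 100 nearest design points (raw Euclidean distance —
all four coordinates share the $[0.1,5]$ scale, so no standardisation) form
the training set of a constant-mean GP with ARD squared-exponential kernel.
Hyperparameters (output scale, four length scales, noise sd) are
re-estimated per query by maximising the log marginal likelihood with
bounded quasi-Newton steps and analytic gradients; the constant mean is
profiled out in closed form. Numerical choices that matter:

* the target column is standardised internally before the likelihood
  optimisation; the noise sd is initialised at $10^{-2}$ (the simulator is
  deterministic; the nugget mostly stabilises the factorisation) and floored
  at $10^{-6}$, both on the standardised scale;
* length-scale inits of half the local data range; if the optimiser falls
  into the degenerate pure-nugget optimum (every length scale at its lower
  bound), one restart from an eighth of the range is attempted and the
  better likelihood kept;
* Cholesky failures trigger jitter escalation (×10 per step up to $10^{-2}$
  of the mean diagonal, then an error).

During loss minimisation the local fit is cached and refreshed only when
the query moves more than half the median nearest-neighbour spacing of the
design; an exact per-query refit is available via `control = list(refit =
"always")`. The cached surrogate is piecewise-smooth; descents therefore use
the analytic gradient of the GP mean, which is exact between refreshes.
Before the Hessian is estimated the cache is re-centred on the optimum so
the whole finite-difference stencil sees one smooth fit.

### Low-rank GP

The design is subsampled to $n_r = 2000$ rows; an isotropic Matérn-3/2
kernel is summed over the pair $(\theta, 1/\theta)$ — the inverse features
capture the steep response near the lower stiffness bound, and $\theta \ge
0.1$ bounds $1/\theta$ — each term with the Kammann–Wand default length
scale (exact maximum pairwise distance on the subsample). The top-$k$
eigenpairs of the subsampled kernel matrix define a finite feature
expansion (Nyström); conventional ranks are $k = 2000$ for output targets
and $k = 1000$ for loss targets, and with $n_r = k = N$ the construction
reproduces exact GP regression with the summed kernel, which is the oracle
used in the tests. One design choice departs from fitting each additive
term separately: a single common output scale multiplies the summed kernel,
so that with the noise variance the marginal likelihood is a two-parameter
problem solved cheaply in the eigenbasis of $Z^\top Z$. A dense symmetric
eigensolver stands in for Lanczos iteration at these sizes ($n_r \le
2000$); the contract is on the returned eigenpairs, not the algorithm.
Predictive variances use the subset-of-regressors form, which is
non-negative and exact in the full-rank limit; how variance was propagated
in the original implementation is not specified, and only those two
properties are relied on.

## Optimisation

The surrogate loss is minimised over $[0.1,5]^4$ by a multistart scheme:
starting points from a Sobol scatter (default 50) are ranked by objective
value and a bounded quasi-Newton descent (PORT/`nlminb`; R's L-BFGS-B is
not reentrant and the objective itself runs L-BFGS-B internally) is run
from each in rank order, capped at 100 iterations, skipping starts inside
the basin of attraction of a previously found minimum — the sphere centred
at that minimum with radius equal to its start-to-minimum distance. In
addition to the Sobol scatter, the few training design rows with the
smallest precomputed loss against $y_0$ are scored as candidate starts, the
analogue of a global-search algorithm's first stage that scores thousands
of trial points before running local solvers. Estimates violating the box
are discarded; the best feasible minimum is returned.

## Uncertainty quantification

The Hessian of the surrogate loss at the optimum is estimated by central
differences with per-dimension step $10^{-4}$ times the box width; it is
symmetrised and repaired to positive definiteness by flooring eigenvalues
at $10^{-10}$ of the largest. Its inverse — an approximate lower bound on
the parameter covariance — parameterises a multivariate normal centred at
the estimate, truncated to the box by rejection (with a clamping fallback
when an essentially unidentified direction makes the acceptance rate
vanish; the accompanying warning is informative, not an error). Fibre- and
sheet-direction stretch–stress curves are evaluated for every sample and
summarised by pointwise 2.5%/97.5% quantiles; the reported band is widened
where necessary to contain the point-estimate curve, so the band always
brackets the estimate. The sample count defaults to 1000; the original
choice is unspecified.

The uniaxial Cauchy stress behind the curves is the exact analytic
derivative $\lambda\, d\Psi/d\lambda$ of the HO energy under incompressible
uniaxial kinematics ($F = \mathrm{diag}(\lambda, \lambda^{-1/2},
\lambda^{-1/2})$ in the material frame) with the hydrostatic pressure
eliminated by the zero-lateral-stress condition; the tension-only
convention switches the $I_{4}$ terms off below unit stretch, so under
fibre loading the sheet term (with $I_{4s} = 1/\lambda < 1$) is inactive
and vice versa. Because $J = 1$ is enforced kinematically the volumetric
penalty contributes nothing to the curves; $K$ is retained only for generic
energy evaluation. The stress unit follows the kPa interpretation of the
a-type constants; the reference source does not state units. Every curve
value is cross-checked in the tests against a finite-difference derivative
of the energy.

## The synthetic simulator: what it emulates and what it does not

The finite-element LV simulator is out of scope; a deterministic analytic
stand-in provides data of the same shape and character. Each of the 24 segments carries a
loading pressure from an increasing grid spanning 0.5–2.0 kPa with a small
deterministic jitter (segments are informative but not identical). The
segment stress is a mixture of the fibre- and sheet-direction uniaxial
responses with per-segment weights in $[0, 0.5]$ — a stand-in for the
transmural rotation of the material axes, and the feature that makes the
anisotropic stiffness and exponent separable — plus a weak fibre–sheet
shear contribution (effective $I_{8fs} = \gamma_j(\lambda - 1)$,
$\gamma_j \in [0.2, 0.8]$) that gives $\theta_4$ a strictly monotone but
1–2 orders weaker influence than the other parameters, mimicking the low
sheet-direction sensitivity of circumferential-strain data. The segment
stretch solves stress = load by vectorised bisection to residuals below
$10^{-8}$ kPa; the reported strain is the Green strain
$(\lambda^2 - 1)/2$ (the source never fixes its strain convention), and
the volume is $V_0 (1 + \overline{\lambda - 1})^3$ with $V_0 = 60$ mL — the
simplest smooth monotone map that produces a differently-scaled 25th
output, which is exactly what stresses the Mahalanobis covariance scaling.
Outputs are strictly decreasing in every $\theta$ component (stiffer tissue
strains less), mutually positively correlated, and the local sensitivities
to the four parameters are strongly collinear — deliberate weak
identifiability. Benchmark test sets are noiseless, as test outputs come
straight from the simulator; optional observation noise defaults to a
strain sd of 0.01 and a volume sd of 1 mL, plausible cine-MRI magnitudes.

A green recovery test therefore establishes that the emulation machinery
inverts a smooth, monotone, weakly identified 25-output forward map of the
true constitutive law at the stated design sizes — not that it reproduces
finite-element LV mechanics, geometry effects, or measurement artefacts.

## Benchmark protocol

`runMethodComparison` runs all eight strategy × interpolator × loss
combinations over a test design that *extends* the training Sobol sequence,
records the parameter-space MSE — fixed as the *mean* of the four squared
errors; rankings are invariant to mean-vs-sum — per test point, retains
non-convergent fits in the distribution (they are the outliers one sees in
practice), and summarises each method by median and quartiles under the
linear-interpolation quantile convention. Individual failures are recorded
with a reason, never fatal. At the desk scale used in the acceptance suite
(2000 training points, 10 test points, 15 optimiser starts) the observed
ranking reproduces the expected pattern: output emulation with the local GP
and Euclidean loss recovers parameters with median MSE well below $10^{-2}$,
output emulation beats loss emulation for the local GP, and the Mahalanobis
loss clearly beats the Euclidean loss within loss emulation — the Euclidean
loss surface is dominated by the volume column's scale, which a single
scalar emulator fits poorly.

## Known limitations

* The toy simulator shares one segment-stress mechanism across outputs;
  real strain fields decorrelate through geometry in ways it cannot mimic.
* $\theta_4$ is close to unidentified by construction; its Hessian-based
  variance is often effectively unbounded and the truncated-normal
  sampling then degenerates towards uniform-in-the-box for that direction.
* The unscrambled, unskipped Sobol default trades randomisation for exact
  cross-run reproducibility; whether the original designs skipped or
  scrambled is unknown and recorded as configuration.
* Hyperparameter refits during optimisation are cached by the refresh-radius
  rule; results can differ at the emulator-error level from the exact
  per-query refit mode (`refit = "always"`).
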