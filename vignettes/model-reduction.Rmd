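---
title: "Profile-likelihood identifiability analysis and model reduction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profile-likelihood identifiability analysis and model reduction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plreduce)
```

## The problem

Mechanistic reaction-network models in systems biology usually carry more
parameters than time-resolved concentration data can constrain. The surplus
shows up as *non-identifiability*: directions in parameter space along which
the model output, restricted to what was measured, barely changes. Such
models fit the data but make imprecise predictions, and their estimates
cannot be summarised by finite confidence intervals.

`plreduce` implements a data-driven reduction workflow built on the profile
likelihood. The model is an ODE system

$$\dot x(t) = f(x(t), \theta_x), \qquad
  y(t) = g(x(t, \theta_x, x_0), \theta_y) + \varepsilon,
  \qquad \varepsilon \sim N(0, \sigma^2),$$

assembled stoichiometrically from reaction rate laws, with observation
functions mapping states (plus observational parameters such as scales) to
the measured quantities. Estimation minimises

$$-2\log L(\theta) = \sum_{i=1}^n
  \left(\frac{y_i - g_i(\theta)}{\sigma_i}\right)^2 + \text{const},$$

over all free parameters on the log10 scale. The *profile likelihood* of a
parameter $\theta_i$ re-optimises every other parameter at each value of
$\theta_i$:

$$\mathrm{PL}(\theta_i) = \min_{\theta_{j \ne i}} \left[-2\log L(\theta)\right].$$

Values of $\theta_i$ with
$\mathrm{PL}(\theta_i) - \min_\theta [-2\log L] \le \chi^2_{\alpha,1}$ form
the profile confidence region; a parameter whose region is unbounded on one
side is *practically non-identifiable*, and one whose profile is flat
everywhere is *structurally non-identifiable*.

The package's contribution is the loop that turns profiles into model
surgery: classify each parameter, read off how the other parameters move
along the open profile direction, choose one of four reduction scenarios,
apply the corresponding structural operator, and validate the result with a
likelihood-ratio test against the unreduced model.

## The four scenarios

A practical non-identifiability opens towards $+\infty$ or $-\infty$ (on the
log scale), and the re-optimised co-parameter paths along the open tail are
either flat or coupled to the scanned parameter. That yields four cases:

* **fast limit, no compensation `(+|)`** — the reaction may be arbitrarily
  fast; merge ("lump") the substrate and product of the conversion into one
  state ([lump_states()]).
* **slow limit, no compensation `(-|)`** — the reaction may be arbitrarily
  slow; delete it ([remove_reaction()]).
* **fast limit, coupled (`+` with compensation)** — a downstream state
  equilibrates instantly against its driver; replace its ODE by an algebraic
  relation, e.g. $pZ = \alpha\, pY$ ([substitute_algebraic()]). Advisory:
  the engine proposes the state and the coupled set, the analyst supplies the
  relation after inspecting trajectories.
* **slow limit, coupled (`-` with compensation)** — typically a pool state
  whose consumption is negligible; freeze it at a constant feeding its
  reactions ([pool_state()]). Advisory, as above; inspect
  [trajectories_along_profile()] first.

A structural non-identifiability is resolved by fixing one parameter of the
compensating group at an arbitrary value ([fix_parameter()]).

Every reduction is checked with the likelihood-ratio statistic
$D = \left[-2\log L\right]_\text{reduced} - \left[-2\log L\right]_\text{full}$
against $\chi^2_\alpha(\max(\Delta\mathrm{dof}, 1))$, where
$\Delta\mathrm{dof}$ counts removed minus introduced free parameters; when a
reduction is parameter-neutral the test conservatively uses one degree of
freedom.

## Numerical design

**Simulation.** Models compile to an ODE right-hand side plus the forward
sensitivity system with respect to the log10 parameters
($\partial x / \partial \log_{10}\theta_k = \theta_k \ln 10 \cdot
\partial x/\partial\theta_k$). Rate laws, inputs and algebraic assignments
are differentiated symbolically, generated as C code, compiled once per
model structure and integrated with `deSolve::lsoda` (rtol $10^{-8}$, atol
$10^{-10}$; the source does not state tolerances, these are package
choices). When no compiler is available the same generated system runs as
plain R functions. Non-negativity is not enforced by projection — that would
distort the sensitivities — tight tolerances are used instead.

**Estimation.** `fit_model()` runs deterministic multi-start trust-region
least squares (`minpack.lm::nls.lm`) with analytic Jacobians from the
forward sensitivities. Starts are Latin-hypercube samples in the log10
bounds (default $[-3, 3]$, 50 starts), reproducible per seed. Ties within
$10^{-8}$ resolve to the lexicographically smallest parameter vector. A
failed integration returns a large finite objective ($10^{10}$) so the
trust region can retreat.

**Profiling.** `profile_likelihood()` scans bidirectionally from the
estimate with warm-started re-optimisation. The step size (log10 units,
within $[10^{-3}, 0.5]$) targets a likelihood increment of
$\chi^2_{0.95,1}/50$ per step: halve on overshoot beyond twice the target,
grow 1.5-fold on undershoot below a fifth. Scans extend 5 log10 units each
way (at most 500 steps); re-optimisation failures halve the step, more than
10 consecutive failures end the direction. Nuisance parameters get the fit
bounds widened by the scan range so compensating parameters can follow the
scan — with plain fit bounds the coupled tails of the fast/slow coupled
scenarios would be truncated and misclassified.

Two deliberate departures from the most literal scan design are worth
recording. First, a direction does not stop the moment its tail looks flat:
flat stretches are cheap (steps grow to the cap), and the full tail is what
the coupling slopes and the structural-non-identifiability evidence are
computed from. Second, a direction does not stop at the first threshold
crossing either: the scanner "coasts" past it to the scan limit, because a
noise-induced barrier (for instance between the two interchangeable optima
of a conversion chain) can exceed the threshold even though the profile
falls back below it further out — the confidence region is then unbounded
and the parameter is still practically non-identifiable. The end status of
a direction is decided from the whole curve: an open tail (back at or below
the threshold at the scan limit) outranks an interior crossing.

Confidence-interval endpoints are the threshold crossings of the profile,
refined by regula falsi on actual re-optimised profile evaluations (plain
linear interpolation on the adaptive grid is kept as a fallback); on
linear-Gaussian problems the refined endpoints reproduce the closed-form
asymptotic intervals to $10^{-6}$. Local minima of a profile are reported
at the vertex of the parabola through the three surrounding grid points,
since the adaptive grid coarsens inside shallow basins.

**Classification.** Co-parameter slopes are least-squares fits of each
re-optimised path against the scanned parameter over the trailing 1.5 log10
units of the open direction (the full scan for structural cases);
$|\text{slope}| < 0.05$ is flat, $> 0.1$ coupled, in between ambiguous and
never auto-acted on. A profile is structural when its total variation stays
below $0.01\,\chi^2_{\alpha,1}$ with no crossing. Tails shorter than 5
points are flagged low-confidence. These thresholds are package choices; the
source literature does not quantify "flattens out" or "coupled".

**The iterative loop.** `auto_reduce()` fits, profiles every free parameter,
classifies, applies the first non-advisory suggestion (structural fixes use
the current estimate), validates it by LRT and repeats until all parameters
are identifiable, a reduction is rejected, or only advisory (coupled)
suggestions remain — those are never applied automatically, mirroring the
flow-chart's insistence that coupled reductions be checked by inspection.

## The example systems

Five fixtures ship with the package (`make_toy()`, `simulate_data()`); each
freezes a ground truth, an observation plan and the expected classification,
so the whole pipeline is testable without external data. Noise levels are
the study conditions (0.1, 0.02, 0.05, 0.1 for the four scenario fixtures);
grids and truths are frozen package choices, printed by `print()` on each
fixture.

```{r toys, eval = FALSE}
fx <- make_toy("cascade1")
fx
d <- simulate_data(fx, seed = 1)
fit <- fit_model(fx$model, d, n_starts = 50, seed = 1)
prof <- profile_likelihood(fx$model, d, fit, "k1")
classify_profile(prof)
analyze_coupling(prof)
```

* `cascade1` — `X -> pX -> ppX`, only `ppX` observed: the two rates are
  interchangeable (exact swap symmetry, two profile optima at the two rate
  estimates) and the first conversion may be arbitrarily fast. The
  observation window runs to $t = 55$, well past the slow timescale
  ($1/k_1 = 10$): the fast-conversion limit differs from the exact two-step
  kinetics by an amplitude shift $k_2/(k_2-k_1)$ of the slow exponential,
  and a shorter window (heavier early sampling) makes that residual misfit
  large enough that noise pushes the profile over the threshold in a
  substantial fraction of replicates, contrary to the scenario this fixture
  exists to exhibit. The window is a compromise: longer windows shrink the
  limit misfit further but degrade the fast-rate estimate that locates the
  upper profile optimum.
* `cascade2_feedback` — a phosphorylation cycle with a weak basal
  dephosphorylation next to a product-mediated feedback. The activation rate
  `k1` is a fixed constant (a known stimulus): left free, it opens a
  fast-exchange compensation branch (`k1`, `k5` growing together) that keeps
  the basal rate's profile below threshold on *both* sides, and no choice of
  truth recovers the intended one-sided pattern.
* `functional_relation` — a driven first layer feeding a fast second layer
  with non-limiting total; the decay rate of the second layer is open
  towards fast values with the production rate compensating at slope $+1$
  (their ratio sets the level), reduced by $pZ = \alpha\,pY$.
* `weak_activation` — an exponentially decaying input drives a weakly
  consumed pool; only the product of `k_on` and the observation scale is
  identifiable (slope $-1$), and after the constant-pool reduction that
  relationship becomes exactly structural, resolved by fixing the scale.
  The truth scale (40) puts the readout's peak near 1.0 so that, at
  $\sigma = 0.1$, the strongly-activated branch (depleting pool) misfits
  decisively while the weak limit stays within noise.
* `mm_conversion` — the enzymatic conversion
  `S + E <-> C -> P + E`; used to demonstrate the emergence of the
  Michaelis-Menten kinetics in the limit of fast complex formation/decay at
  fixed ratio (`make_mm_limit_model()` provides the limit model). The enzyme
  total (0.01 of the substrate) keeps substrate sequestration negligible so
  the distance to the limit is dominated by the finite rates.

## What the generator does and does not emulate

`simulate_data()` adds independent, homoscedastic Gaussian noise with known
per-point standard deviation to error-free trajectories of a perfectly
specified model. Real time-course data (e.g. quantified immunoblots)
additionally carry multiplicative and correlated errors, unknown and
point-dependent variances, normalisation artefacts, and — most importantly —
model misspecification. Passing tests on these fixtures therefore
demonstrate that the machinery recovers the right answers when the model
family is correct and the error model is known; they do not certify
performance under misspecification. The likelihood-ratio validation in
particular inherits the usual caveat that it can only reject reductions
against *observed* components: removing unobserved but biologically relevant
structure may pass the test and still bias predictions.

A related caveat is intrinsic to the test itself: a valid limit-reduction is
rejected in roughly a $1-\alpha$ fraction of noise realisations by
construction. Across many replicates occasional rejections of correct
reductions are expected and observed; re-profiling after a rejection is the
right response in practice.

## Degenerate inputs and edge behaviour

Models with all rates zero simulate as constants; profiles of models with a
single free parameter skip the (empty) nuisance re-optimisation; reductions
that orphan parameters drop them from the free set automatically, since the
free set is derived from the expressions; fixing an already-fixed parameter
warns and returns the model unchanged; a reduced fit that beats the full fit
by more than a statistically irrelevant margin ($10^{-3}$, absorbing the
boundary effect of bounded fits whose superfluous rate stops at the log10
bound) raises a nesting error rather than reporting a negative statistic.
Integration failures anywhere in the pipeline carry the parameter point and
degrade gracefully: the optimiser retreats, the profiler flags the point and
halves the step, and only ten consecutive failures end a scan direction.

## Problem sizes

The shipped analyses are sized for a desk machine: fixtures have 2-4 dynamic
states and 1-5 free parameters, datasets 12-32 points, multi-starts 10-50,
and the replicate suites use 20 classification seeds, 10 validation seeds
and 200 coverage replicates. All of these are package choices, reported
where they are used.
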