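# plreduce

Profile-likelihood identifiability analysis and data-driven model reduction
for ODE reaction-network models.

## The problem

Mechanistic ODE models of biochemical networks — phosphorylation cascades,
enzyme kinetics, signalling pathways — are routinely over-parameterised
relative to the time-resolved concentration data available to calibrate
them. The surplus manifests as **non-identifiability**: directions in
parameter space along which the observed model output barely changes, so
parameters have no finite confidence intervals and predictions are
imprecise. `plreduce` is for modellers who want to *shrink* such a model to
the complexity their data actually supports, while keeping every state and
rate mechanistically interpretable.

## The method

A model is an ODE system assembled stoichiometrically from reaction rate
laws, x'(t) = f(x, θ_x), observed through y(t) = g(x(t), θ_y) + ε with
additive Gaussian errors. Fitting minimises the scaled negative
log-likelihood

    -2 log L(θ) = Σ_i ((y_i − g_i(θ)) / σ_i)²

over all free parameters on the log10 scale, by deterministic multi-start
trust-region least squares with analytic Jacobians from forward
sensitivities. The **profile likelihood** of a parameter θ_i,

    PL(θ_i) = min over θ_{j≠i} of −2 log L(θ),

re-optimises all other parameters at each scan point; the region where
PL − min ≤ χ²(α, 1) is the profile confidence region. Each parameter is
classified as identifiable, practically non-identifiable (region open on one
side), or structurally non-identifiable (profile flat). For an open
direction, the re-optimised co-parameter paths reveal whether other
parameters compensate, yielding four reduction scenarios:

| scenario | limit | co-parameters | reduction |
|---|---|---|---|
| `(+\|)` | fast | flat | lump the conversion's states (`lump_states`) |
| `(-\|)` | slow | flat | delete the reaction (`remove_reaction`) |
| `(+` coupled `)` | fast | compensating | algebraic relation for the downstream state (`substitute_algebraic`, advisory) |
| `(-` coupled `)` | slow | compensating | freeze the pool state at a constant (`pool_state`, advisory) |

Structural non-identifiabilities are resolved by fixing one parameter of the
compensating group (`fix_parameter`). Every reduction is validated by a
likelihood-ratio test of the reduced against the full model,
D = ΔL ≤ χ²(α, max(Δdof, 1)). `auto_reduce()` iterates
fit → profile → classify → reduce → test until every parameter is
identifiable; coupled-scenario suggestions are advisory and never applied
automatically.

Five example systems ship with the package (`make_toy`, `simulate_data`),
one per scenario plus the enzymatic conversion whose fast-rate limit is the
Michaelis–Menten kinetics.

## Worked example

The two-step conversion cascade `X -> pX -> ppX` with only `ppX` observed
(σ = 0.1) is the classic case of an unobserved intermediate:

```r
library(plreduce)

fx  <- make_toy("cascade1")
d   <- simulate_data(fx, seed = 1)
fit <- fit_model(fx$model, d, n_starts = 50, seed = 1)
fit
#> <fit_result: objective 13.894, 50 start(s)>
#>   k1           log10 =  -0.9090   natural = 0.123312
#>   k2           log10 =  -0.2882   natural = 0.514983

prof <- profile_likelihood(fx$model, d, fit, "k1")
confidence_interval(prof)
#> 95% CI for log10(k1): [-1.089, Inf]
classify_profile(prof)
#> k1: practically_NI_upper  CI(log10) = [-1.089, Inf]
analyze_coupling(prof)
#>   parameter         slope label
#> 1        k2 -5.922708e-05  flat
suggest_scenario(classify_profile(prof), analyze_coupling(prof), fx$model)
#> <scenario (+|) for k1: lump_states>
#>   rate may be arbitrarily fast: lump the states X and pX
```

The first rate is open towards +∞ — the data never exclude an arbitrarily
fast first step — and `k2` does not compensate, so the states `X` and `pX`
are merged. The likelihood-ratio test confirms the one-step model describes
the data equally well, and its remaining rate is identifiable:

```r
red  <- lump_states(fx$model, "r1")
rfit <- fit_model(red, d, n_starts = 10, seed = 1)
likelihood_ratio_test(fit, rfit)
#> LRT: D = 1.047 vs chi2(0.95, dof 1) = 3.841 -> accepted
classify_profile(profile_likelihood(red, d, rfit, "k2"))
#> k2: identifiable  CI(log10) = [-1.103, -0.8988]
```

The profile of `k1` also exhibits the two interchangeable optima of the
chain (`profile_local_minima(prof)`), at the two rate estimates — a
signature of the swap symmetry when the intermediate is unobserved. The
same loop runs unattended via `auto_reduce()`, and from the shell via the
CLI script (`inst/cli/plreduce`): subcommands `simulate`, `fit`, `profile`,
`classify`, `reduce`, `lrt`, `auto`.

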