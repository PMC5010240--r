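# Small model builders shared across tests. All fixtures are constructed in
# code; no files are read.

# one-state exponential decay, identity observation
decay_model <- function(sigma = 0.1, x0 = 1) {
  model_spec("decay", states = "x", initials = list(x = x0),
             reactions = "x -> ; k * x",
             observables = c(y = "x"), errors = list(y = sigma))
}

decay_data <- function(k = 0.5, sigma = 0.1, times = seq(0.5, 5, length.out = 10),
                       seed = 1, noise = TRUE) {
  m <- decay_model(sigma)
  pred <- x0_decay(k, times)
  if (noise) {
    set.seed(seed)
    val <- pred + rnorm(length(times), 0, sigma)
  } else val <- pred
  dataset(data.frame(observable = "y", time = times, value = val,
                     sigma = sigma), m)
}

x0_decay <- function(k, times, x0 = 1) x0 * exp(-k * times)

# observation-only model: y = theta for every record (no dynamics)
constant_model <- function(sigma = 0.5) {
  model_spec("constant", states = "dummy", initials = list(dummy = 0),
             observables = c(y = "theta"), errors = list(y = sigma))
}

constant_data <- function(values, sigma = 0.5, times = seq_along(values)) {
  dataset(data.frame(observable = "y", time = times, value = values,
                     sigma = sigma))
}

# irreversible two-step chain with shared rate (closed-form oracle available)
chain_model <- function() {
  model_spec("chain", states = c("X", "pX", "ppX"), initials = list(X = 1),
             reactions = c("X -> pX ; k1 * X", "pX -> ppX ; k2 * pX"),
             observables = c(ppX_obs = "ppX"), errors = list(ppX_obs = 0.1))
}

# linear-Gaussian observation model y = a + b * t (for the normal-equations
# oracle); parameters positive so the log10 parameterisation applies
linear_model <- function(sigma = 0.2) {
  model_spec("linear", states = "dummy", initials = list(dummy = 0),
             observables = c(y = "a + b * t"), errors = list(y = sigma))
}

# relative/absolute comparison used for sensitivity checks
expect_close <- function(actual, expected, rtol = 1e-4, atol = 1e-6) {
  err <- abs(actual - expected)
  bound <- rtol * abs(expected) + atol
  expect_true(all(err <= bound),
              label = sprintf("max excess %.3g", max(err - bound)))
}

# central finite differences of the states w.r.t. log10 parameters; the
# solver runs well below the comparison tolerance so the oracle's own noise
# (~rtol/h) stays negligible
fd_sensitivities <- function(model, params, times, h = 1e-4) {
  cmp_states <- function(p)
    simulate_model(model, p, times, rtol = 1e-11, atol = 1e-13)$states
  free <- names(params)
  base <- cmp_states(params)
  dyn <- dynamic_states(model)
  out <- array(NA_real_, c(length(times), length(dyn), length(free)),
               dimnames = list(NULL, dyn, free))
  for (k in free) {
    up <- params; up[[k]] <- up[[k]] + h
    dn <- params; dn[[k]] <- dn[[k]] - h
    out[, , k] <- (cmp_states(up)[, dyn] - cmp_states(dn)[, dyn]) / (2 * h)
  }
  out
}
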