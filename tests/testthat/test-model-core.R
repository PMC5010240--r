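# Model representation, ODE assembly, simulation and forward sensitivities.

test_that("stoichiometric assembly gives mass-action dynamics and is deterministic", {
  m <- model_spec("conv", states = c("X", "pX"), initials = list(X = 2),
                  reactions = "X -> pX ; k1 * X",
                  observables = c(y = "pX"), errors = list(y = 0.1))
  f <- assemble_odes(m)
  v <- f(c(X = 2, pX = 0), c(k1 = 0.3))
  expect_equal(unname(v), c(-0.6, 0.6))
  # assembling twice is identical
  f2 <- assemble_odes(m)
  expect_identical(v, f2(c(X = 2, pX = 0), c(k1 = 0.3)))
  S <- stoichiometry(m)
  expect_identical(S, stoichiometry(m))
  expect_equal(unname(S[, 1]), c(-1L, 1L))
})

test_that("all-zero rate constants freeze the simulation", {
  m <- model_spec("frozen", states = c("A", "B"), initials = list(A = 1, B = 2),
                  reactions = c("A -> B ; k1 * A", "B -> A ; k2 * B"),
                  observables = c(y = "A"), errors = list(y = 0.1),
                  fixed = c(k1 = 0, k2 = 0))
  tr <- simulate_model(m, parameter_vector(setNames(numeric(), character())),
                       seq(0, 10, 1))
  expect_true(all(abs(tr$states[, "A"] - 1) < 1e-10))
  expect_true(all(abs(tr$states[, "B"] - 2) < 1e-10))
})

test_that("model invariants are enforced with informative errors", {
  expect_error(model_spec("bad", states = "X",
                          reactions = "X -> ; k * X * unknown_sym",
                          observables = c(y = "X"), errors = list(y = 0.1)),
               NA)  # unknown_sym is a legal free parameter
  expect_error(model_spec("bad", states = c("X", "Y"),
                          reactions = "X -> Y ; k * X",
                          observables = c(y = "X"), errors = list(y = 0.1),
                          assignments = c(Y = "2 * X")),
               "algebraically assigned")
  expect_error(model_spec("bad", states = "X", observables = c(y = "X"),
                          assignments = c(X = "X + 1")),
               "references itself")
  expect_error(model_spec("dup", states = c("X", "X"),
                          observables = c(y = "X")),
               "duplicate state")
})

test_that("one-state decay matches the closed form", {
  m <- decay_model()
  p <- as_log10_parameters(c(k = 0.5), m)
  tr <- simulate_model(m, p, c(2))
  expect_close(unname(tr$states[1, "x"]), exp(-1), rtol = 1e-6, atol = 0)
})

test_that("irreversible chain matches the two-exponential closed form", {
  m <- chain_model()
  times <- seq(0.5, 20, length.out = 17)
  # distinct rates
  p <- as_log10_parameters(c(k1 = 0.3, k2 = 0.8), m)
  tr <- simulate_model(m, p, times)
  closed <- 1 - (0.8 * exp(-0.3 * times) - 0.3 * exp(-0.8 * times)) / 0.5
  expect_close(tr$states[, "ppX"], closed, rtol = 1e-6, atol = 1e-9)
  # equal rates (confluent limit)
  pe <- as_log10_parameters(c(k1 = 0.4, k2 = 0.4), m)
  tre <- simulate_model(m, pe, times)
  closed_eq <- 1 - exp(-0.4 * times) * (1 + 0.4 * times)
  expect_close(tre$states[, "ppX"], closed_eq, rtol = 1e-6, atol = 1e-9)
})

test_that("algebraic assignments replace the ODE and feed observables", {
  m <- model_spec("reduced3", states = c("pY", "pZ"),
                  initials = list(pY = 1),
                  reactions = "pY -> ; k_dY * pY",
                  observables = c(pZ_obs = "pZ"),
                  errors = list(pZ_obs = 0.05),
                  assignments = c(pZ = "alpha * pY"))
  expect_identical(dynamic_states(m), "pY")
  expect_setequal(free_parameters(m), c("k_dY", "alpha"))
  p <- as_log10_parameters(c(k_dY = 0.5, alpha = 2), m)
  times <- seq(0, 4, 0.5)
  tr <- simulate_model(m, p, times)
  expect_close(tr$states[, "pZ"], 2 * tr$states[, "pY"], rtol = 1e-12,
               atol = 1e-12)
  g <- observe_model(m, tr, p)
  expect_equal(unname(g[, "pZ_obs"]), unname(tr$states[, "pZ"]))
})

test_that("observation map evaluates expressions pointwise without noise", {
  fx <- make_toy("weak_activation")
  times <- seq(0, 20, 2)
  tr <- simulate_model(fx$model, fx$truth, times)
  g <- observe_model(fx$model, tr, fx$truth)
  manual <- 10^fx$truth[["scale"]] * tr$states[, "pX"]  # scale * pX
  expect_close(unname(g[, "pX_obs"]), unname(manual), rtol = 1e-12, atol = 0)
  # doubling an observation parameter doubles the series
  p2 <- fx$truth
  p2[["scale"]] <- fx$truth[["scale"]] + log10(2)
  g2 <- observe_model(fx$model, tr, p2)
  expect_close(unname(g2[, "pX_obs"]), 2 * unname(g[, "pX_obs"]),
               rtol = 1e-12, atol = 0)
})

test_that("closed conversion chains conserve mass", {
  for (nm in c("cascade1", "cascade2_feedback")) {
    fx <- make_toy(nm)
    tr <- simulate_model(fx$model, fx$truth, seq(0, 40, 1))
    total <- rowSums(tr$states[, dynamic_states(fx$model)])
    expect_true(all(abs(total - total[[1]]) < 1e-6), label = nm)
  }
})

test_that("sensitivities vanish at t = 0 for kinetic parameters and carry the log10 chain rule for initials", {
  m <- model_spec("decay_x0", states = "x", initials = list(x = "x0"),
                  reactions = "x -> ; k * x",
                  observables = c(y = "x"), errors = list(y = 0.1))
  p <- as_log10_parameters(c(k = 0.5, x0 = 2), m)
  ss <- simulate_sensitivities(m, p, c(0, 1, 2))
  expect_equal(ss$sens[1, "x", "k"], 0)
  expect_equal(ss$sens[1, "x", "x0"], 2 * log(10), tolerance = 1e-10)
})

test_that("decay sensitivity matches the hand-derived formula", {
  m <- decay_model()
  k <- 0.5
  times <- seq(0.5, 4, 0.5)
  ss <- simulate_sensitivities(m, as_log10_parameters(c(k = k), m), times)
  expected <- -times * k * log(10) * exp(-k * times)
  expect_close(ss$sens[, "x", "k"], expected, rtol = 1e-6, atol = 1e-10)
})

test_that("analytic sensitivities agree with central finite differences", {
  fx <- make_toy("cascade1")
  times <- seq(2, 30, length.out = 8)
  set.seed(42)
  for (i in 1:3) {
    p <- fx$truth + rnorm(length(fx$truth), 0, 0.2)
    ss <- simulate_sensitivities(fx$model, p, times)
    fd <- fd_sensitivities(fx$model, p, times)
    expect_close(ss$sens, fd, rtol = 1e-4, atol = 1e-6)
  }
})

test_that("integration failure raises a typed condition carrying the parameters", {
  m <- model_spec("blowup", states = "x", initials = list(x = 1),
                  reactions = "-> x ; k * x * x",
                  observables = c(y = "x"), errors = list(y = 0.1))
  p <- as_log10_parameters(c(k = 100), m)
  err <- tryCatch(simulate_model(m, p, c(1, 5)),
                  integration_error = function(e) e)
  expect_s3_class(err, "integration_error")
  expect_false(is.null(err$params))
})

test_that("time grids must be strictly increasing and non-negative", {
  m <- decay_model()
  p <- as_log10_parameters(c(k = 0.5), m)
  expect_error(simulate_model(m, p, c(2, 1)), "strictly increasing")
  expect_error(simulate_model(m, p, c(-1, 1)), "strictly increasing")
})
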