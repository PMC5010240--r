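# The -2 log L objective, the residual/Jacobian pair and the multi-start
# trust-region fit.

test_that("dataset validation rejects malformed records", {
  expect_error(dataset(data.frame(observable = "y", time = 1, value = 1)),
               "missing column")
  expect_error(dataset(data.frame(observable = "y", time = 1, value = 1,
                                  sigma = 0)),
               "non-positive sigma in dataset row 1")
  expect_error(dataset(data.frame(observable = "z", time = 1, value = 1,
                                  sigma = 0.1), decay_model()),
               "unknown observable")
  expect_error(dataset(data.frame(observable = character(), time = numeric(),
                                  value = numeric(), sigma = numeric())),
               "at least one record")
})

test_that("objective is zero for exact predictions and quadratic otherwise", {
  m <- decay_model()
  d <- decay_data(k = 0.5, noise = FALSE)
  p <- as_log10_parameters(c(k = 0.5), m)
  expect_lt(neg2_log_likelihood(m, d, p), 1e-10)

  # single-point arithmetic: ((1 - 0.8)/0.1)^2 = 4
  mc <- constant_model(sigma = 0.1)
  dc <- dataset(data.frame(observable = "y", time = 1, value = 1, sigma = 0.1))
  expect_equal(neg2_log_likelihood(mc, dc, as_log10_parameters(c(theta = 0.8))),
               4, tolerance = 1e-12)
})

test_that("objective equals a brute-force summation over records", {
  fx <- make_toy("cascade2_feedback")
  d <- simulate_data(fx, seed = 7)
  p <- fx$truth + 0.05
  val <- neg2_log_likelihood(fx$model, d, p)
  # independent re-summation from the predicted series
  times <- sort(unique(d$time))
  g <- observe_model(fx$model, simulate_model(fx$model, p, times), p)
  acc <- 0
  for (i in seq_len(nrow(d))) {
    pred <- unname(g[match(d$time[[i]], times), d$observable[[i]]])
    acc <- acc + ((d$value[[i]] - pred) / d$sigma[[i]])^2
  }
  expect_equal(val, acc, tolerance = 1e-12)
})

test_that("weighted residuals square-sum to the objective and the Jacobian matches finite differences", {
  fx <- make_toy("cascade1")
  d <- simulate_data(fx, seed = 3)
  p <- fx$truth + c(0.1, -0.1)
  rj <- residuals_and_jacobian(fx$model, d, p)
  expect_false(rj$failed)
  expect_equal(sum(rj$residuals^2), neg2_log_likelihood(fx$model, d, p),
               tolerance = 1e-8)
  h <- 1e-5
  for (k in names(p)) {
    up <- p; up[[k]] <- up[[k]] + h
    dn <- p; dn[[k]] <- dn[[k]] - h
    fd <- (residuals_and_jacobian(fx$model, d, up)$residuals -
           residuals_and_jacobian(fx$model, d, dn)$residuals) / (2 * h)
    expect_close(rj$jacobian[, k], fd, rtol = 1e-4, atol = 1e-6)
  }
})

test_that("for an identity observable the Jacobian collapses to -sensitivity/sigma", {
  m <- decay_model(sigma = 0.2)
  d <- decay_data(k = 0.5, sigma = 0.2, noise = FALSE)
  p <- as_log10_parameters(c(k = 0.5), m)
  rj <- residuals_and_jacobian(m, d, p)
  ss <- simulate_sensitivities(m, p, d$time)
  expect_close(rj$jacobian[, "k"], -ss$sens[, "x", "k"] / 0.2,
               rtol = 1e-8, atol = 1e-12)
})

test_that("a start at the truth recovers it exactly on noise-free data", {
  m <- decay_model()
  d <- decay_data(k = 0.5, noise = FALSE)
  f <- fit_model(m, d, n_starts = 1,
                 starts = matrix(log10(0.5), 1, 1), seed = 1)
  expect_lt(f$objective, 1e-6)
  expect_equal(as.numeric(f$theta_hat[["k"]]), log10(0.5), tolerance = 1e-6)
})

test_that("the constant model estimate is the sample mean", {
  y <- c(4.1, 5.2, 4.7, 5.5, 4.9)
  m <- constant_model(sigma = 0.5)
  d <- constant_data(y, sigma = 0.5)
  f <- fit_model(m, d, n_starts = 10, bounds = c(-1, 2), seed = 1)
  expect_equal(10^as.numeric(f$theta_hat[["theta"]]), mean(y),
               tolerance = 1e-7)
  expect_equal(f$objective, sum((y - mean(y))^2) / 0.5^2, tolerance = 1e-8)
})

test_that("a two-parameter linear-Gaussian fit matches the normal equations", {
  times <- seq(1, 6)
  set.seed(11)
  y <- 2 + 0.8 * times + rnorm(6, 0, 0.2)
  m <- linear_model(sigma = 0.2)
  d <- dataset(data.frame(observable = "y", time = times, value = y,
                          sigma = 0.2))
  f <- fit_model(m, d, n_starts = 15, bounds = c(-2, 2), seed = 1)
  X <- cbind(1, times)
  beta <- solve(crossprod(X), crossprod(X, y))
  expect_equal(10^as.numeric(f$theta_hat[["a"]]), beta[[1]], tolerance = 1e-8)
  expect_equal(10^as.numeric(f$theta_hat[["b"]]), beta[[2]], tolerance = 1e-8)
})

test_that("fits are byte-identical for a repeated seed", {
  fx <- make_toy("cascade1")
  d <- simulate_data(fx, seed = 5)
  f1 <- fit_model(fx$model, d, n_starts = 6, seed = 42)
  f2 <- fit_model(fx$model, d, n_starts = 6, seed = 42)
  expect_identical(f1, f2)
  f3 <- fit_model(fx$model, d, n_starts = 6, seed = 43)
  expect_false(identical(f3$multistart, f1$multistart))
})

test_that("the best objective is a multi-start plateau on every toy", {
  for (nm in c("cascade1", "cascade2_feedback", "functional_relation",
               "weak_activation")) {
    fx <- make_toy(nm)
    d <- simulate_data(fx, seed = 1)
    f <- fit_model(fx$model, d, n_starts = 50, seed = 1)
    n_at_best <- sum(f$multistart$objective <= f$objective + 1e-4)
    expect_gte(n_at_best, 2)
  }
})

test_that("integration failures during optimisation retreat instead of aborting", {
  m <- model_spec("fragile", states = "x", initials = list(x = 1),
                  reactions = "-> x ; k * x * x",
                  observables = c(y = "x"), errors = list(y = 0.1))
  d <- dataset(data.frame(observable = "y", time = c(1, 2, 4),
                          value = c(1.1, 1.3, 1.9), sigma = 0.1), m)
  # large k blows up in finite time; the sentinel keeps the optimiser alive
  f <- fit_model(m, d, n_starts = 8, bounds = c(-3, 3), seed = 2)
  expect_true(is.finite(f$objective))
  expect_lt(f$objective, 1e9)
})

test_that("the reported objective is reproducible from the estimate", {
  fx <- make_toy("functional_relation")
  d <- simulate_data(fx, seed = 2)
  f <- fit_model(fx$model, d, n_starts = 8, seed = 1)
  expect_equal(as.numeric(neg2_log_likelihood(fx$model, d, f$theta_hat)),
               f$objective, tolerance = 1e-6)
})
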