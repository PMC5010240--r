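# The four reduction operators and the likelihood-ratio test.

test_that("lumping merges a conversion pair and drops the orphaned rate", {
  fx <- make_toy("cascade1")
  red <- lump_states(fx$model, "r1")
  expect_setequal(red$states, c("X_pX", "ppX"))
  expect_length(red$reactions, 1)
  expect_identical(free_parameters(red), "k2")
  expect_equal(red$initials[["X_pX"]], 1)
  # state count decreases by exactly one
  expect_equal(length(red$states), length(fx$model$states) - 1)
  # the rewired reaction consumes the merged state
  expect_identical(red$reactions[[1]]$substrates, "X_pX")
})

test_that("lumping rejects bimolecular reactions and reversible pairs", {
  mm <- make_toy("mm_conversion")$model
  expect_error(lump_states(mm, "r1"), "not a unimolecular conversion")
  expect_error(lump_states(mm, "nope"), "no reaction with id")
  rev <- model_spec("rev", states = c("A", "B"), initials = list(A = 1),
                    reactions = c("A -> B ; kf * A", "B -> A ; kr * B"),
                    observables = c(y = "B"), errors = list(y = 0.1))
  expect_error(lump_states(rev, "r1"), "reverse reaction")
})

test_that("removing a zero-rate reaction leaves trajectories unchanged", {
  m <- model_spec("withdead", states = c("A", "B"), initials = list(A = 1),
                  reactions = c("A -> B ; k1 * A", "B -> A ; k0 * B"),
                  observables = c(y = "B"), errors = list(y = 0.1),
                  fixed = c(k0 = 0))
  red <- remove_reaction(m, "r2")
  p <- as_log10_parameters(c(k1 = 0.4))
  times <- seq(0, 10, 0.5)
  t1 <- simulate_model(m, p, times)
  t2 <- simulate_model(red, p, times)
  expect_true(all(abs(t1$states[, c("A", "B")] -
                      t2$states[, c("A", "B")]) < 1e-10))
})

test_that("reaction removal drops exactly the orphaned parameters", {
  fx <- make_toy("cascade2_feedback")
  before <- free_parameters(fx$model)
  red <- remove_reaction(fx$model, "r4")
  after <- free_parameters(red)
  expect_setequal(setdiff(before, after), "k4")
  expect_equal(length(fx$model$reactions) - length(red$reactions), 1)
  expect_identical(red$states, fx$model$states)
})

test_that("algebraic substitution moves the state out of the ODE system and registers new parameters", {
  fx <- make_toy("functional_relation")
  red <- substitute_algebraic(fx$model, "pZ", "alpha * pY")
  expect_false("pZ" %in% dynamic_states(red))
  expect_true("pZ" %in% names(red$assignments))
  expect_setequal(free_parameters(red), c("k_aY", "k_dY", "alpha"))
  # pZ observable now follows the assignment
  p <- as_log10_parameters(c(k_aY = 2, k_dY = 0.3, alpha = 0.9), red)
  tr <- simulate_model(red, p, seq(0, 20, 2))
  g <- observe_model(red, tr, p)
  expect_close(unname(g[, "pZ_obs"]), 0.9 * unname(tr$states[, "pY"]),
               rtol = 1e-12, atol = 0)
})

test_that("substituting a state by its own closed-form solution preserves predictions", {
  m <- model_spec("twostate", states = c("x", "z"), initials = list(x = 1),
                  reactions = c("x -> ; kx * x", "-> z ; kz * x"),
                  observables = c(y = "z"), errors = list(y = 0.1),
                  fixed = c(kx = 0.5))
  p <- as_log10_parameters(c(kz = 2))
  times <- seq(0, 8, 0.5)
  g_full <- observe_model(m, simulate_model(m, p, times), p)
  red <- substitute_algebraic(m, "x", "exp(-0.5 * t)")
  g_red <- observe_model(red, simulate_model(red, p, times), p)
  expect_close(g_red[, "y"], g_full[, "y"], rtol = 1e-7, atol = 1e-9)
})

test_that("substitution guards against self-reference and cycles", {
  fx <- make_toy("functional_relation")
  expect_error(substitute_algebraic(fx$model, "pZ", "2 * pZ"),
               "references the state itself")
  red <- substitute_algebraic(fx$model, "pZ", "alpha * pY")
  expect_error(substitute_algebraic(red, "pY", "pZ / alpha"),
               "cyclic")
  expect_error(substitute_algebraic(fx$model, "nostate", "1"),
               "not a dynamic state")
})

test_that("the constant-pool operator keeps reactions and freezes the pool", {
  fx <- make_toy("weak_activation")
  red <- pool_state(fx$model, "X")
  expect_identical(dynamic_states(red), "pX")
  expect_identical(red$assignments[["X"]], "1")
  expect_length(red$reactions, 2)
  # pX dynamics now see the constant pool
  p <- fx$truth
  tr <- simulate_model(red, p, seq(0, 20, 2))
  expect_true(all(abs(tr$states[, "X"] - 1) < 1e-12))
})

test_that("fixing parameters is a bookkeeping no-op at the estimate", {
  fx <- make_toy("cascade1")
  d <- simulate_data(fx, seed = 1)
  f <- fit_model(fx$model, d, n_starts = 8, seed = 1)
  red <- fix_parameter(fx$model, "k1",
                       10^as.numeric(f$theta_hat[["k1"]]))
  expect_identical(free_parameters(red), "k2")
  start <- matrix(as.numeric(f$theta_hat[["k2"]]), 1, 1)
  f2 <- fit_model(red, d, n_starts = 1, starts = start, seed = 1)
  expect_equal(f2$objective, f$objective, tolerance = 1e-6)
  expect_warning(fix_parameter(red, "k1", 1), "already fixed")
  expect_error(fix_parameter(fx$model, "zzz", 1), "not a free parameter")
})

test_that("the likelihood-ratio test accepts equal fits and enforces nesting", {
  fake_fit <- function(obj, free) structure(list(objective = obj, free = free),
                                            class = "fit_result")
  lrt <- likelihood_ratio_test(fake_fit(10, c("a", "b")), fake_fit(10, "a"))
  expect_equal(lrt$D, 0)
  expect_true(lrt$accepted)
  expect_equal(lrt$delta_dof, 1)
  # conservative dof floor when the reduction is parameter-neutral
  lrt0 <- likelihood_ratio_test(fake_fit(10, c("a", "b")),
                                fake_fit(11, c("c", "d")))
  expect_equal(lrt0$dof_used, 1)
  expect_error(likelihood_ratio_test(fake_fit(10, "a"), fake_fit(9.5, "a")),
               "beat the full fit")
  expect_error(likelihood_ratio_test(fake_fit(10, "a"),
                                     fake_fit(10, c("a", "b"))),
               "not nested")
})

test_that("reduced models round-trip through the YAML format unchanged", {
  fx1 <- make_toy("cascade1")
  reductions <- list(
    lump_states(fx1$model, "r1"),
    remove_reaction(make_toy("cascade2_feedback")$model, "r4"),
    substitute_algebraic(make_toy("functional_relation")$model, "pZ",
                         "alpha * pY"),
    pool_state(make_toy("weak_activation")$model, "X"),
    fix_parameter(fx1$model, "k1", 0.1))
  for (red in reductions) {
    path <- tempfile(fileext = ".yaml")
    write_model_yaml(red, path)
    back <- read_model_yaml(path)
    expect_equal(unclass(back), unclass(red), label = red$name)
    unlink(path)
  }
})
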