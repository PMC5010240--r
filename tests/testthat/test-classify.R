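# Identifiability trichotomy, coupling analysis and scenario mapping.

# build a synthetic pl_profile with prescribed grid/PL/paths/statuses
fake_profile <- function(param, grid, pl, paths = NULL, status_lo, status_up,
                         objective = min(pl), alpha = 0.95, theta = NULL) {
  cols <- c(setdiff(colnames(paths), param), param)
  path <- matrix(NA_real_, length(grid), length(cols),
                 dimnames = list(NULL, cols))
  path[, param] <- grid
  if (!is.null(paths)) for (p in colnames(paths)) path[, p] <- paths[, p]
  if (is.null(theta)) theta <- stats::setNames(grid[which.min(pl)], param)
  structure(list(param = param, grid = grid, pl = pl, path = path,
                 objective = objective, alpha = alpha,
                 threshold = objective + chi2_threshold(alpha, 1),
                 end_status = c(lower = status_lo, upper = status_up),
                 refined = c(lower = NA_real_, upper = NA_real_),
                 theta_hat = parameter_vector(theta),
                 step_config = profile_step_config()),
            class = "pl_profile")
}

test_that("the trichotomy classifies parabolic, one-sided and flat profiles", {
  g <- seq(-2, 2, 0.05)
  parab <- fake_profile("p", g, 3 * g^2, status_lo = "crossed_threshold",
                        status_up = "crossed_threshold")
  expect_identical(classify_profile(parab)$class, "identifiable")
  expect_true(is.finite(classify_profile(parab)$ci$lower))

  upper_open <- fake_profile("p", g, pmin(3 * (g + 1.5)^2, 2),
                             status_lo = "crossed_threshold",
                             status_up = "flattened")
  expect_identical(classify_profile(upper_open)$class, "practically_NI_upper")
  expect_identical(classify_profile(upper_open)$ci$upper, Inf)

  lower_open <- fake_profile("p", g, pmin(3 * (g - 1.5)^2, 2),
                             status_lo = "flattened",
                             status_up = "crossed_threshold")
  expect_identical(classify_profile(lower_open)$class, "practically_NI_lower")
  expect_identical(classify_profile(lower_open)$ci$lower, -Inf)

  flat <- fake_profile("p", g, rep(1, length(g)) + 1e-5 * g,
                       status_lo = "flattened", status_up = "flattened",
                       objective = 1 - 1e-5)
  expect_identical(classify_profile(flat)$class, "structurally_NI")

  failed <- fake_profile("p", g, 3 * g^2, status_lo = "integration_failed",
                         status_up = "integration_failed")
  expect_identical(classify_profile(failed)$class, "inconclusive")
  expect_null(classify_profile(failed)$ci)
})

test_that("coupling slopes are labelled flat, coupled or ambiguous by threshold", {
  g <- seq(0, 3, 0.1)
  pl <- pmin(4 * (g - 0)^2, 1)  # flattens upward
  paths <- cbind(comp = 5 - g,          # slope -1: coupled
                 still = rep(2, length(g)) + 0.02 * g,  # slope 0.02: flat
                 mid = 0.075 * g)       # slope 0.075: ambiguous
  pr <- fake_profile("p", g, pl, paths, "crossed_threshold", "flattened")
  cp <- analyze_coupling(pr)
  expect_identical(attr(cp, "direction"), "upper")
  expect_identical(cp$label[cp$parameter == "comp"], "coupled")
  expect_equal(cp$slope[cp$parameter == "comp"], -1, tolerance = 1e-10)
  expect_identical(cp$label[cp$parameter == "still"], "flat")
  expect_identical(cp$label[cp$parameter == "mid"], "ambiguous")
})

test_that("short tails are flagged low-confidence", {
  g <- c(0, 0.5, 2.2, 2.8)
  pl <- c(5, 1, 1, 1)
  paths <- cbind(q = c(0, 0, 0, 0))
  pr <- fake_profile("p", g, pl, paths, "crossed_threshold", "flattened")
  cp <- analyze_coupling(pr, tolerances = classifier_tolerances(tail_window = 1))
  expect_true(attr(cp, "low_confidence"))
})

test_that("coupling analysis refuses a two-sided identifiable profile", {
  g <- seq(-1, 1, 0.1)
  pr <- fake_profile("p", g, 10 * g^2, status_lo = "crossed_threshold",
                     status_up = "crossed_threshold")
  expect_error(analyze_coupling(pr), "crossed the threshold")
})

test_that("scenario mapping follows the flow chart", {
  fx <- make_toy("cascade1")
  ident <- structure(list(parameter = "k1", class = "practically_NI_upper",
                          ci = NULL), class = "identifiability_report")
  cp_flat <- structure(data.frame(parameter = "k2", slope = 0.001,
                                  label = "flat"),
                       direction = "upper",
                       class = c("coupling_report", "data.frame"))
  sg <- suggest_scenario(ident, cp_flat, fx$model)
  expect_identical(sg$scenario, "(+|)")
  expect_identical(sg$action, "lump_states")
  expect_identical(sg$reaction_id, "r1")
  expect_false(sg$advisory)
  expect_setequal(sg$states, c("X", "pX"))

  fx2 <- make_toy("cascade2_feedback")
  ident2 <- structure(list(parameter = "k4", class = "practically_NI_lower",
                           ci = NULL), class = "identifiability_report")
  cp2 <- structure(data.frame(parameter = c("k2", "k3", "k5"),
                              slope = c(0, 0, 0), label = "flat"),
                   direction = "lower",
                   class = c("coupling_report", "data.frame"))
  sg2 <- suggest_scenario(ident2, cp2, fx2$model)
  expect_identical(sg2$scenario, "(-|)")
  expect_identical(sg2$action, "remove_reaction")
  expect_identical(sg2$reaction_id, "r4")

  fx3 <- make_toy("functional_relation")
  ident3 <- structure(list(parameter = "k_dZ", class = "practically_NI_upper",
                           ci = NULL), class = "identifiability_report")
  cp3 <- structure(data.frame(parameter = c("k_aY", "k_dY", "k_Z"),
                              slope = c(0, 0, 1),
                              label = c("flat", "flat", "coupled")),
                   direction = "upper",
                   class = c("coupling_report", "data.frame"))
  sg3 <- suggest_scenario(ident3, cp3, fx3$model)
  expect_identical(sg3$scenario, paste0("(+", "\u2195", ")"))
  expect_identical(sg3$action, "substitute_algebraic")
  expect_true(sg3$advisory)
  expect_identical(sg3$states, "pZ")
  expect_identical(sg3$coupled, "k_Z")

  fx4 <- make_toy("weak_activation")
  ident4 <- structure(list(parameter = "k_on", class = "practically_NI_lower",
                           ci = NULL), class = "identifiability_report")
  cp4 <- structure(data.frame(parameter = c("k_off", "scale"),
                              slope = c(0, -1),
                              label = c("flat", "coupled")),
                   direction = "lower",
                   class = c("coupling_report", "data.frame"))
  sg4 <- suggest_scenario(ident4, cp4, fx4$model)
  expect_identical(sg4$scenario, paste0("(-", "\u2195", ")"))
  expect_identical(sg4$action, "inspect_trajectories")
  expect_true(sg4$advisory)
  expect_identical(sg4$coupled, "scale")
  expect_identical(sg4$states, "X")

  # structural non-identifiability resolves by fixing the parameter
  ident5 <- structure(list(parameter = "scale", class = "structurally_NI",
                           ci = NULL), class = "identifiability_report")
  sg5 <- suggest_scenario(ident5, cp4, fx4$model)
  expect_identical(sg5$action, "fix_parameter")
  expect_false(sg5$advisory)

  # a pure observation parameter with no coupling can only be fixed
  mobs <- model_spec("obsonly", states = "x", initials = list(x = 1),
                     reactions = "x -> ; k * x",
                     observables = c(y = "offset + x"),
                     errors = list(y = 0.1))
  ident6 <- structure(list(parameter = "offset",
                           class = "practically_NI_lower", ci = NULL),
                      class = "identifiability_report")
  cp6 <- structure(data.frame(parameter = "k", slope = 0, label = "flat"),
                   direction = "lower",
                   class = c("coupling_report", "data.frame"))
  sg6 <- suggest_scenario(ident6, cp6, mobs)
  expect_identical(sg6$action, "fix_parameter")
  expect_match(sg6$note, "no reaction")

  # identifiable parameters yield no suggestion
  ident7 <- structure(list(parameter = "k", class = "identifiable", ci = NULL),
                      class = "identifiability_report")
  expect_error(suggest_scenario(ident7, cp6, mobs), "identifiable")
})

test_that("trajectories along the profile expose the limit behaviour", {
  fx <- make_toy("weak_activation")
  d <- simulate_data(fx, seed = 1)
  f <- fit_model(fx$model, d, n_starts = 8, seed = 1)
  pr <- profile_likelihood(fx$model, d, f, "k_on")
  times <- seq(0, 20, 1)

  single <- trajectories_along_profile(fx$model, pr, times, n_points = 1)
  expect_length(single, 1)
  expect_equal(single[[1]]$scan_value,
               as.numeric(f$theta_hat[["k_on"]]), tolerance = 0.05)

  fam <- trajectories_along_profile(fx$model, pr, times, n_points = 9)
  expect_length(fam, 9)
  scans <- vapply(fam, `[[`, 0, "scan_value")
  x_range <- vapply(fam, function(e) diff(range(e$trajectory$states[, "X"])),
                    numeric(1))
  # X(t) flattens towards a constant pool as k_on decreases
  expect_lt(x_range[[which.min(scans)]], 0.02)
  expect_gt(x_range[[which.max(scans)]], 0.1)
})
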