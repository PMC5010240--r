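# The five example systems shipped with the package: a Michaelis-Menten
# enzyme conversion (used for the fast-limit convergence property) and four
# small signalling cascades, one per reduction scenario. Each fixture fixes
# the ground-truth parameters, the observation plan (observables, time grid,
# Gaussian noise level) and the expected classification, so the whole
# pipeline is testable without external data.

.TOY_NAMES <- c("mm_conversion", "cascade1", "cascade2_feedback",
                "functional_relation", "weak_activation")

#' Construct one of the shipped example fixtures
#'
#' Fixtures (noise levels are part of the study design; all other numbers are
#' frozen package choices):
#' \describe{
#'   \item{cascade1}{`X -> pX -> ppX`, only `ppX` observed (sigma 0.1), truth
#'     `k1 = 0.1`, `k2 = 1`: the unobserved intermediate makes the two rates
#'     interchangeable and `k1` practically non-identifiable towards fast
#'     values, with no compensation  -- scenario `(+|)`, reduced by lumping
#'     `X` and `pX`.}
#'   \item{cascade2_feedback}{cycle `X -> pX -> ppX -> X` with a weak basal
#'     dephosphorylation `pX -> X` (`k4`) next to a `ppX`-mediated feedback
#'     (`k5`); `X` and `pX` observed (sigma 0.02): `k4` is non-identifiable
#'     towards slow values with flat co-parameters  -- scenario `(-|)`, reduced
#'     by removing the basal reaction.}
#'   \item{functional_relation}{driven phosphorylation `Y <-> pY` feeding a
#'     fast second layer `pZ` (production `k_Z`, decay `k_dZ`, non-limiting
#'     total); `pY` and `pZ` observed (sigma 0.05): `k_dZ` is
#'     non-identifiable towards fast values with `k_Z` compensating at slope
#'     +1  -- scenario `(+` coupled `)`, reduced by the algebraic relation
#'     `pZ = alpha * pY`.}
#'   \item{weak_activation}{`X <-> pX` driven by an exponentially decaying
#'     input with small `k_on`, observed as `scale * pX` (sigma 0.1): `k_on`
#'     is non-identifiable towards small values with `scale` compensating at
#'     slope -1  -- scenario `(-` coupled `)`, reduced by treating `X` as a
#'     constant pool, after which the residual `(k_on, scale)` relation is
#'     structural and one of them is fixed.}
#'   \item{mm_conversion}{`S + E <-> C -> P + E`; demonstrates the emergence
#'     of the Michaelis-Menten limit as complex formation/decay become fast
#'     at fixed ratio. Used for convergence properties, not classification.}
#' }
#'
#' @param name one of `r paste0('"', paste(.TOY_NAMES, collapse = '", "'), '"')`
#' @return object of class `toy_fixture`: `model`, `truth` (log10),
#'   `plan` (observable/time/sigma), `expected_scenario`, `expected_param`,
#'   `expected_reduction`
#' @export
make_toy <- function(name) {
  if (!name %in% .TOY_NAMES)
    stop(sprintf("unknown toy '%s'; valid names: %s", name,
                 paste(.TOY_NAMES, collapse = ", ")), call. = FALSE)
  fx <- switch(name,
    cascade1 = {
      model <- model_spec("cascade1",
        states = c("X", "pX", "ppX"),
        initials = list(X = 1, pX = 0, ppX = 0),
        reactions = c("X -> pX ; k1 * X",
                      "pX -> ppX ; k2 * pX"),
        observables = c(ppX_obs = "ppX"),
        errors = list(ppX_obs = 0.1))
      # the window extends well past the slow-rate timescale so the fast
      # conversion limit describes the data within noise (its residual
      # amplitude-shift misfit decays with the observation horizon)
      list(model = model,
           truth = c(k1 = 0.1, k2 = 1),
           plan = expand_plan("ppX_obs", seq(0, 55, length.out = 15), 0.1),
           expected_scenario = paste0("(+", "|", ")"),
           expected_param = "k1",
           expected_reduction = list(action = "lump_states", reaction_id = "r1"))
    },
    cascade2_feedback = {
      # k1 is the known stimulus strength: leaving it free admits a
      # fast-exchange compensation branch (k1, k5 growing with k4) that keeps
      # the basal rate's profile open in both directions
      model <- model_spec("cascade2_feedback",
        states = c("X", "pX", "ppX"),
        initials = list(X = 1, pX = 0, ppX = 0),
        reactions = c("X -> pX ; k1 * X",
                      "pX -> ppX ; k2 * pX",
                      "ppX -> X ; k3 * ppX",
                      "pX -> X ; k4 * pX",
                      "pX + ppX -> X + ppX ; k5 * pX * ppX"),
        observables = c(X_obs = "X", pX_obs = "pX"),
        errors = list(X_obs = 0.02, pX_obs = 0.02),
        fixed = c(k1 = 1))
      times <- seq(0, 40, length.out = 16)
      list(model = model,
           truth = c(k2 = 0.5, k3 = 0.3, k4 = 0.01, k5 = 2),
           plan = rbind(expand_plan("X_obs", times, 0.02),
                        expand_plan("pX_obs", times, 0.02)),
           expected_scenario = paste0("(-", "|", ")"),
           expected_param = "k4",
           expected_reduction = list(action = "remove_reaction",
                                     reaction_id = "r4"))
    },
    functional_relation = {
      model <- model_spec("functional_relation",
        states = c("Y", "pY", "pZ"),
        initials = list(Y = 1, pY = 0, pZ = 0),
        reactions = c("Y -> pY ; k_aY * u * Y",
                      "pY -> Y ; k_dY * pY",
                      "-> pZ ; k_Z * pY * (Z_tot - pZ)",
                      "pZ -> ; k_dZ * pZ"),
        inputs = c(u = "exp(-0.2 * t)"),
        observables = c(pY_obs = "pY", pZ_obs = "pZ"),
        errors = list(pY_obs = 0.05, pZ_obs = 0.05),
        fixed = c(Z_tot = 1000))
      times <- seq(0, 20, length.out = 12)
      # Z_tot is genuinely non-limiting (pZ stays ~0.1% of the total), so the
      # fast-limit prediction set contains the exact linear relation
      # pZ = alpha * pY that the reduction substitutes (the relative
      # saturation of the second layer is alpha * pY / Z_tot)
      list(model = model,
           truth = c(k_aY = 2, k_dY = 0.3, k_Z = 0.1, k_dZ = 100),
           plan = rbind(expand_plan("pY_obs", times, 0.05),
                        expand_plan("pZ_obs", times, 0.05)),
           expected_scenario = paste0("(+", "\u2195", ")"),
           expected_param = "k_dZ",
           expected_reduction = list(action = "substitute_algebraic",
                                     state = "pZ", expression = "alpha * pY"))
    },
    weak_activation = {
      model <- model_spec("weak_activation",
        states = c("X", "pX"),
        initials = list(X = 1, pX = 0),
        reactions = c("X -> pX ; k_on * u * X",
                      "pX -> X ; k_off * pX"),
        inputs = c(u = "exp(-0.1 * t)"),
        observables = c(pX_obs = "scale * pX"),
        errors = list(pX_obs = 0.1))
      # scale sets the signal-to-noise of the scaled readout; at peak
      # observation ~1 the strongly activated (depleting-pool) branch
      # misfits decisively while the weak limit stays within noise
      list(model = model,
           truth = c(k_on = 0.01, k_off = 0.2, scale = 40),
           plan = expand_plan("pX_obs", seq(0, 20, length.out = 12), 0.1),
           expected_scenario = paste0("(-", "\u2195", ")"),
           expected_param = "k_on",
           expected_reduction = list(action = "pool_state", state = "X",
                                     then_fix = c(scale = 1)))
    },
    mm_conversion = {
      # enzyme total well below substrate so the quasi-steady-state error is
      # dominated by the finite complex formation/decay rates, not by
      # substrate sequestration
      model <- model_spec("mm_conversion",
        states = c("S", "E", "C", "P"),
        initials = list(S = 1, E = 0.01, C = 0, P = 0),
        reactions = c("S + E -> C ; k_plus * S * E",
                      "C -> S + E ; k_minus * C",
                      "C -> P + E ; k2 * C"),
        observables = c(P_obs = "P"),
        errors = list(P_obs = 0.05))
      list(model = model,
           truth = c(k_plus = 10, k_minus = 10, k2 = 10),
           plan = expand_plan("P_obs", seq(0, 10, length.out = 15), 0.05),
           expected_scenario = NA_character_,
           expected_param = NA_character_,
           expected_reduction = NULL)
    })
  fx$name <- name
  fx$truth <- as_log10_parameters(fx$truth, fx$model)
  structure(fx, class = "toy_fixture")
}

#' @keywords internal
expand_plan <- function(observable, times, sigma) {
  data.frame(observable = observable, time = times, sigma = sigma,
             stringsAsFactors = FALSE)
}

#' Valid toy fixture names
#' @export
toy_names <- function() .TOY_NAMES

#' Generate a synthetic dataset from a fixture
#'
#' Simulates the fixture at its ground truth and adds independent additive
#' Gaussian noise with the observation plan's per-point sigma. Deterministic
#' for a fixed seed.
#'
#' @param fixture a `toy_fixture` (or a toy name)
#' @param seed integer seed
#' @return a `pl_dataset`
#' @export
simulate_data <- function(fixture, seed = 1L) {
  if (is.character(fixture)) fixture <- make_toy(fixture)
  stopifnot(inherits(fixture, "toy_fixture"))
  plan <- fixture$plan
  times <- sort(unique(plan$time))
  traj <- simulate_model(fixture$model, fixture$truth, times)
  g <- observe_model(fixture$model, traj, fixture$truth)
  pred <- g[cbind(match(plan$time, times),
                  match(plan$observable, colnames(g)))]
  set.seed(seed)
  value <- pred + stats::rnorm(nrow(plan), mean = 0, sd = plan$sigma)
  dataset(data.frame(observable = plan$observable, time = plan$time,
                     value = value, sigma = plan$sigma,
                     stringsAsFactors = FALSE), fixture$model)
}

#' The Michaelis-Menten limit model of the enzymatic conversion
#'
#' The reduced kinetics `dP/dt = k2 * E_tot * S / (Km + S)` that emerges from
#' the full mass-action mechanism when complex formation and decay are fast
#' at fixed ratio `Km = k_minus / k_plus`.
#'
#' @param Km,k2,E_tot,S0 kinetic constants and totals (natural scale)
#' @return a `model_spec` with states `S`, `P`
#' @export
make_mm_limit_model <- function(Km = 1, k2 = 10, E_tot = 0.01, S0 = 1) {
  model_spec("mm_limit",
    states = c("S", "P"),
    initials = list(S = S0, P = 0),
    reactions = "S -> P ; k2 * E_tot * S / (Km + S)",
    observables = c(P_obs = "P"),
    errors = list(P_obs = 0.05),
    fixed = c(Km = Km, k2 = k2, E_tot = E_tot))
}

#' @export
print.toy_fixture <- function(x, ...) {
  cat(sprintf("<toy_fixture '%s'>\n", x$name))
  print(x$model)
  cat(sprintf("  truth (log10) : %s\n",
              paste(sprintf("%s=%.3g", names(x$truth), as.numeric(x$truth)),
                    collapse = ", ")))
  cat(sprintf("  plan          : %d points, sigma %s\n", nrow(x$plan),
              paste(unique(x$plan$sigma), collapse = "/")))
  if (!is.na(x$expected_scenario))
    cat(sprintf("  expected      : %s on %s\n", x$expected_scenario,
                x$expected_param))
  invisible(x)
}
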