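# The four structural reduction operators. Each takes a model_spec and
# returns a new, validated model_spec; free parameters that no longer occur
# anywhere simply drop out of the free set, which is derived from the
# expressions. Reductions are validated against the data by a likelihood-ratio
# test of the reduced fit against the full fit.

#' @keywords internal
find_reaction <- function(model, reaction_id) {
  ids <- vapply(model$reactions, `[[`, "", "id")
  i <- match(reaction_id, ids)
  if (is.na(i))
    stop(sprintf("no reaction with id '%s' (have: %s)", reaction_id,
                 paste(ids, collapse = ", ")), call. = FALSE)
  i
}

#' @keywords internal
rebuild_model <- function(model, states = model$states,
                          initials = model$initials,
                          reactions = vapply(model$reactions, format_reaction,
                                             character(1L)),
                          inputs = model$inputs,
                          observables = model$observables,
                          errors = model$errors,
                          assignments = model$assignments,
                          fixed = model$fixed,
                          name = model$name) {
  # drop error entries for observables that no longer exist, etc.
  errors <- errors[names(errors) %in% names(observables)]
  model_spec(name = name, states = states, initials = initials,
             reactions = unlist(reactions, use.names = FALSE),
             inputs = unlist(inputs), observables = unlist(observables),
             errors = errors, assignments = unlist(assignments), fixed = fixed)
}

#' Substitute a state symbol throughout a model's expressions
#' @keywords internal
rename_symbol <- function(text, from, to) {
  subs <- stats::setNames(list(as.name(to)), from)
  deparse1_(substitute_expr(parse_expr(text), subs))
}

#' Lump two states connected by a fast conversion reaction
#'
#' Merges the substrate and product of a unimolecular conversion `A -> B`
#' into a single state named `A_B` (initial condition: sum of the two),
#' deletes the fast reaction and rewires every other reaction, observable and
#' assignment to the merged state. Parameters that become orphaned drop out
#' of the free set.
#'
#' @param model a `model_spec`
#' @param reaction_id id of the conversion reaction considered arbitrarily
#'   fast
#' @return the reduced `model_spec`
#' @export
lump_states <- function(model, reaction_id) {
  i <- find_reaction(model, reaction_id)
  rx <- model$reactions[[i]]
  if (length(rx$substrates) != 1L || length(rx$products) != 1L ||
      rx$substrates[[1L]] == rx$products[[1L]])
    stop(sprintf("reaction %s is not a unimolecular conversion A -> B; lumping is unsupported (consider an algebraic substitution instead)",
                 reaction_id), call. = FALSE)
  a <- rx$substrates[[1L]]
  b <- rx$products[[1L]]
  # a reversible partner makes the pair an equilibrium, not a fast conversion
  for (other in model$reactions[-i]) {
    if (identical(other$substrates, rx$products) &&
        identical(other$products, rx$substrates))
      stop(sprintf("reaction %s has a reverse reaction (%s); lumping a reversible pair is unsupported (consider an algebraic substitution instead)",
                   reaction_id, other$id), call. = FALSE)
  }
  merged <- paste(a, b, sep = "_")
  if (merged %in% model$states)
    merged <- paste0(merged, "_lumped")

  ia <- model$initials[[a]]
  ib <- model$initials[[b]]
  merged_init <- if (is.numeric(ia) && is.numeric(ib)) ia + ib
    else if (is.character(ia) && is.numeric(ib) && ib == 0) ia
    else if (is.character(ib) && is.numeric(ia) && ia == 0) ib
    else stop("cannot merge the initial conditions of ", a, " and ", b,
              " (both parameterised)", call. = FALSE)

  states <- model$states
  states[states == a] <- merged
  states <- setdiff(states, b)
  initials <- model$initials[setdiff(names(model$initials), c(a, b))]
  initials[[merged]] <- merged_init

  rewire <- function(v) { v[v == a] <- merged; v[v == b] <- merged; unique(v) }
  reactions <- lapply(model$reactions[-i], function(r) {
    r$substrates <- rewire(r$substrates)
    r$products <- rewire(r$products)
    r$rate <- rename_symbol(rename_symbol(r$rate, a, merged), b, merged)
    format_reaction(r)
  })
  observables <- lapply(model$observables, function(g)
    rename_symbol(rename_symbol(g, a, merged), b, merged))
  assignments <- lapply(model$assignments, function(g)
    rename_symbol(rename_symbol(g, a, merged), b, merged))

  rebuild_model(model, states = states, initials = initials,
                reactions = reactions, observables = observables,
                assignments = assignments)
}

#' Remove a reaction from a model
#'
#' Deletes the reaction; states are untouched and parameters occurring
#' nowhere else drop out of the free set.
#' @param model a `model_spec`
#' @param reaction_id reaction to remove
#' @return the reduced `model_spec`
#' @export
remove_reaction <- function(model, reaction_id) {
  i <- find_reaction(model, reaction_id)
  rebuild_model(model,
                reactions = lapply(model$reactions[-i], format_reaction))
}

#' Replace a state's ODE by an algebraic relation
#'
#' Moves the state from the ODE system to the algebraic assignments and
#' re-resolves observables against the assignment. By default every reaction
#' producing or consuming the state is deleted (the state's kinetics are
#' entirely replaced by the relation); with `drop_reactions = FALSE` the
#' reactions are kept and the state is only removed from their stoichiometry,
#' so its symbol in the rate laws resolves to the assignment (the
#' constant-pool limit, see [pool_state()]). Unknown symbols in the
#' expression that are not states or inputs are registered as new free
#' parameters.
#'
#' @param model a `model_spec`
#' @param state dynamic state to replace
#' @param expression replacement expression, e.g. `"alpha * pY"`
#' @param drop_reactions delete reactions touching the state (default) or
#'   keep them with the state removed from their stoichiometry
#' @return the reduced `model_spec`
#' @export
substitute_algebraic <- function(model, state, expression,
                                 drop_reactions = TRUE) {
  if (!state %in% dynamic_states(model))
    stop(sprintf("'%s' is not a dynamic state of the model", state),
         call. = FALSE)
  syms <- expr_symbols(expression, "replacement expression")
  if (state %in% syms)
    stop(sprintf("replacement expression for '%s' references the state itself",
                 state), call. = FALSE)
  chain <- syms
  seen <- state
  # walk assignment references to detect cycles through other assigned states
  while (length(chain)) {
    nxt <- intersect(chain, names(model$assignments))
    if (any(nxt %in% seen) || state %in% chain)
      stop("algebraic substitution would create a cyclic assignment",
           call. = FALSE)
    seen <- c(seen, nxt)
    chain <- unique(unlist(lapply(nxt, function(s)
      expr_symbols(model$assignments[[s]]))))
  }
  assignments <- c(model$assignments, stats::setNames(list(expression), state))
  if (drop_reactions) {
    keep <- vapply(model$reactions, function(rx)
      !(state %in% c(rx$substrates, rx$products)), logical(1L))
    reactions <- lapply(model$reactions[keep], format_reaction)
  } else {
    reactions <- list()
    for (rx in model$reactions) {
      rx$substrates <- setdiff(rx$substrates, state)
      rx$products <- setdiff(rx$products, state)
      if (!length(rx$substrates) && !length(rx$products)) next  # now a no-op
      reactions <- c(reactions, format_reaction(rx))
    }
  }
  rebuild_model(model, reactions = reactions, assignments = assignments)
}

#' Constant-pool reduction of a state
#'
#' The slow-coupled limit: consumption of the pool state is negligible, so the
#' state is frozen at a constant (its initial value by default) that feeds its
#' reactions, and its ODE is dropped. A special case of
#' [substitute_algebraic()] that keeps the reactions.
#'
#' @param model a `model_spec`
#' @param state the pool state
#' @param value constant level; defaults to the state's (literal) initial
#'   condition
#' @return the reduced `model_spec`
#' @export
pool_state <- function(model, state, value = NULL) {
  if (is.null(value)) {
    value <- model$initials[[state]]
    if (!is.numeric(value))
      stop(sprintf("initial condition of '%s' is not a literal; supply a value",
                   state), call. = FALSE)
  }
  substitute_algebraic(model, state, format(as.numeric(value), digits = 15),
                       drop_reactions = FALSE)
}

#' Fix a free parameter at a literal value
#'
#' The parameter becomes a constant (natural scale) inlined into the model;
#' the free count decreases by one. Fixing an already-fixed parameter is a
#' no-op with a warning.
#'
#' @param model a `model_spec`
#' @param param free parameter name
#' @param value natural-scale value (> 0 not required: the constant is no
#'   longer estimated on the log scale)
#' @return the reduced `model_spec`
#' @export
fix_parameter <- function(model, param, value) {
  if (param %in% names(model$fixed)) {
    warning(sprintf("parameter '%s' is already fixed at %g; no-op",
                    param, model$fixed[[param]]))
    return(model)
  }
  if (!param %in% free_parameters(model))
    stop(sprintf("'%s' is not a free parameter of the model", param),
         call. = FALSE)
  fixed <- c(model$fixed, stats::setNames(as.numeric(value), param))
  # an initial condition referencing the parameter becomes the literal value
  initials <- model$initials
  for (s in names(initials)) {
    if (is.character(initials[[s]]) && initials[[s]] == param)
      initials[[s]] <- as.numeric(value)
  }
  rebuild_model(model, initials = initials, fixed = fixed)
}

#' Likelihood-ratio test of a reduced model against the full model
#'
#' The statistic is `D = L_reduced - L_full` on the -2 log L scale; the
#' reduction is accepted when `D` stays below the chi-square quantile with
#' `max(delta_dof, 1)` degrees of freedom (a conservative floor when the
#' reduction removes as many parameters as it introduces).
#'
#' @param full_fit,reduced_fit `fit_result` objects of the nested pair
#' @param delta_dof difference in free-parameter count; defaults to the count
#'   difference of the two fits
#' @param alpha test level
#' @param nest_tol tolerance on negative `D` before the nesting/optimisation
#'   inconsistency error is raised. The default absorbs the boundary effect
#'   of bounded fits: a full model whose superfluous rate sits at the log10
#'   lower bound can trail the exact nested limit by a statistically
#'   irrelevant margin (well below the chi-square decision scale).
#' @return object of class `lrt_result`: `D`, `delta_dof`, `dof_used`,
#'   `critical`, `accepted`, `alpha`
#' @export
likelihood_ratio_test <- function(full_fit, reduced_fit, delta_dof = NULL,
                                  alpha = 0.95, nest_tol = 0.05) {
  D <- reduced_fit$objective - full_fit$objective
  if (is.null(delta_dof))
    delta_dof <- length(full_fit$free) - length(reduced_fit$free)
  if (delta_dof < 0L)
    stop("reduced model has more free parameters than the full model; not nested",
         call. = FALSE)
  if (D < -nest_tol)
    stop(sprintf("reduced fit beat the full fit (D = %.3g): nesting or optimisation inconsistency; refit the full model with more starts",
                 D), call. = FALSE)
  dof_used <- max(delta_dof, 1L)
  critical <- chi2_threshold(alpha, dof_used)
  structure(list(D = max(D, 0), delta_dof = delta_dof, dof_used = dof_used,
                 critical = critical, accepted = D <= critical, alpha = alpha),
            class = "lrt_result")
}

#' @export
print.lrt_result <- function(x, ...) {
  cat(sprintf("LRT: D = %.4g vs chi2(%.2f, dof %d) = %.4g -> %s\n",
              x$D, x$alpha, x$dof_used, x$critical,
              if (x$accepted) "accepted" else "REJECTED"))
  invisible(x)
}

#' Apply a reduction suggestion to a model
#'
#' Dispatcher used by the pipeline: `lump_states` and `remove_reaction` are
#' applied from the suggestion's reaction; `fix_parameter` fixes the
#' parameter at the supplied value (default: its current estimate);
#' `substitute_algebraic` requires the user-supplied relation in `expression`
#' (the engine proposes the state, not the formula).
#'
#' @param model a `model_spec`
#' @param suggestion a `scenario_suggestion`
#' @param value natural-scale value for `fix_parameter`
#' @param expression replacement expression for `substitute_algebraic`
#' @param state target state override for `substitute_algebraic`
#' @return the reduced `model_spec`
#' @export
apply_suggestion <- function(model, suggestion, value = NULL,
                             expression = NULL, state = NULL) {
  switch(suggestion$action,
    lump_states = lump_states(model, suggestion$reaction_id),
    remove_reaction = remove_reaction(model, suggestion$reaction_id),
    fix_parameter = {
      if (is.null(value))
        stop("fix_parameter requires a value (e.g. the current estimate)",
             call. = FALSE)
      fix_parameter(model, suggestion$parameter, value)
    },
    substitute_algebraic = {
      if (is.null(expression))
        stop("substitute_algebraic requires the user-supplied relation; the suggestion only proposes the state",
             call. = FALSE)
      substitute_algebraic(model, state %||% suggestion$states[[1L]], expression)
    },
    inspect_trajectories =
      stop("inspect_trajectories is advisory: examine trajectories_along_profile() and choose a reduction explicitly",
           call. = FALSE),
    stop("unknown action: ", suggestion$action, call. = FALSE))
}
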