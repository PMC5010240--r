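# ModelSpec: declarative representation of an ODE reaction network with an
# observation model. States evolve by mass-balance over reactions; observables
# map states (plus observational parameters) to measured quantities; algebraic
# assignments replace a state's ODE by a closed-form relation (used by reduced
# models). All free parameters are estimated on the log10 scale, so they must
# be positive on the natural scale.

.RESERVED <- c(.TIME_SYMBOL, "pi", "T", "F")

#' Construct a reaction-network model specification
#'
#' @param name model name.
#' @param states character vector of dynamic state names (ordered, unique).
#' @param initials named list/vector; one entry per state: either a numeric
#'   literal or a character string naming a free initial-condition parameter.
#'   Defaults to 0 for states not listed.
#' @param reactions character vector of reaction strings
#'   `"A + B -> C ; rate_expression"`. Either side may be empty
#'   (synthesis/degradation), e.g. `"pZ -> ; k_dZ * pZ"`. States appearing in
#'   the rate but on neither side act as modifiers.
#' @param inputs named character vector of time-dependent input expressions
#'   (functions of `t` and, optionally, fixed parameters), e.g.
#'   `c(u = "exp(-0.1 * t)")`.
#' @param observables named character vector of observation expressions over
#'   states, assigned states and observational parameters.
#' @param errors named list; one entry per observable: `"data"` (per-datapoint
#'   sigma taken from the dataset; the default), a positive numeric literal, or
#'   a character string naming a free sigma parameter.
#' @param assignments named character vector mapping a state name to an
#'   algebraic expression over the remaining states/parameters/inputs.
#'   Assigned states are removed from the ODE system.
#' @param fixed named numeric vector of parameters held at literal values
#'   (natural scale); they are inlined at compile time.
#'
#' @return an object of class `model_spec`
#' @export
model_spec <- function(name, states, initials = NULL, reactions = character(),
                       inputs = character(), observables, errors = NULL,
                       assignments = character(), fixed = numeric()) {
  stopifnot(is.character(states), length(states) >= 1L)
  if (anyDuplicated(states))
    stop("duplicate state names: ",
         paste(unique(states[duplicated(states)]), collapse = ", "), call. = FALSE)
  init <- as.list(rep(0, length(states)))
  names(init) <- states
  if (!is.null(initials)) {
    initials <- as.list(initials)
    bad <- setdiff(names(initials), states)
    if (length(bad))
      stop("initial condition for unknown state: ", paste(bad, collapse = ", "),
           call. = FALSE)
    init[names(initials)] <- initials
  }
  rx <- lapply(seq_along(reactions), function(i)
    parse_reaction(reactions[[i]], i))
  obs <- as.list(observables)
  if (is.null(names(obs)) || any(!nzchar(names(obs))))
    stop("observables must be a named character vector", call. = FALSE)
  err <- as.list(rep("data", length(obs)))
  names(err) <- names(obs)
  if (!is.null(errors)) {
    errors <- as.list(errors)
    bad <- setdiff(names(errors), names(obs))
    if (length(bad))
      stop("error model for unknown observable: ", paste(bad, collapse = ", "),
           call. = FALSE)
    err[names(errors)] <- errors
  }
  mdl <- structure(list(
    name = as.character(name),
    states = states,
    initials = init,
    reactions = rx,
    inputs = as.list(inputs),
    observables = obs,
    errors = err,
    assignments = as.list(assignments),
    fixed = fixed
  ), class = "model_spec")
  validate_model_spec(mdl)
  mdl
}

#' Parse a single reaction string "A + B -> C ; rate"
#' @keywords internal
parse_reaction <- function(text, index = NA_integer_) {
  stopifnot(is.character(text), length(text) == 1L)
  parts <- strsplit(text, ";", fixed = TRUE)[[1L]]
  if (length(parts) != 2L)
    stop(sprintf("reaction %s ('%s'): expected 'A -> B ; rate_expression'",
                 index, text), call. = FALSE)
  eq <- trimws(parts[[1L]])
  rate <- trimws(parts[[2L]])
  sides <- strsplit(eq, "->", fixed = TRUE)[[1L]]
  if (length(sides) > 2L || length(sides) < 1L)
    stop(sprintf("reaction %s ('%s'): exactly one '->' expected", index, text),
         call. = FALSE)
  split_side <- function(s) {
    s <- trimws(s)
    if (!nzchar(s) || s == "0") return(character())
    out <- trimws(strsplit(s, "+", fixed = TRUE)[[1L]])
    out[nzchar(out)]
  }
  substrates <- split_side(sides[[1L]])
  products <- if (length(sides) == 2L) split_side(sides[[2L]]) else character()
  parse_expr(rate, sprintf("rate of reaction %s", index))  # syntax check
  out <- list(id = sprintf("r%d", index), substrates = substrates,
              products = products, rate = rate, text = NULL)
  out$text <- format_reaction(out)  # canonical form, so round trips are exact
  out
}

#' Reconstruct the canonical reaction string for a parsed reaction
#' @keywords internal
format_reaction <- function(rx) {
  lhs <- if (length(rx$substrates)) paste(rx$substrates, collapse = " + ") else ""
  rhs <- if (length(rx$products)) paste(rx$products, collapse = " + ") else ""
  sprintf("%s -> %s ; %s", lhs, rhs, rx$rate)
}

#' States acting as modifiers of a reaction (in the rate, on neither side)
#' @keywords internal
reaction_modifiers <- function(rx, states) {
  setdiff(intersect(expr_symbols(rx$rate), states),
          c(rx$substrates, rx$products))
}

#' Dynamic states (ODE system) of a model
#' @export
dynamic_states <- function(model) setdiff(model$states, names(model$assignments))

#' Free parameters of a model, in canonical order
#'
#' Canonical order: parameters first appearing in reaction rates (by reaction
#' order), then free initial conditions, then assignment expressions, then
#' observables, then free sigma parameters.
#' @export
free_parameters <- function(model) {
  known <- c(model$states, names(model$inputs), names(model$fixed), .RESERVED)
  grab <- function(text, where) setdiff(expr_symbols(text, where), known)
  out <- character()
  for (rx in model$reactions) out <- c(out, grab(rx$rate, "rate"))
  for (s in names(model$initials)) {
    v <- model$initials[[s]]
    if (is.character(v)) out <- c(out, v)
  }
  for (s in names(model$assignments)) out <- c(out, grab(model$assignments[[s]], "assignment"))
  for (o in names(model$observables)) out <- c(out, grab(model$observables[[o]], "observable"))
  for (o in names(model$errors)) {
    v <- model$errors[[o]]
    if (is.character(v) && !identical(v, "data")) out <- c(out, v)
  }
  unique(out)
}

#' Names of free sigma parameters
#' @keywords internal
sigma_parameters <- function(model) {
  out <- character()
  for (o in names(model$errors)) {
    v <- model$errors[[o]]
    if (is.character(v) && !identical(v, "data")) out <- c(out, v)
  }
  unique(out)
}

#' Validate a model specification
#'
#' Checks that every symbol in every expression resolves to exactly one state,
#' free parameter, fixed parameter, input or the time variable, and that no
#' state is simultaneously dynamic and algebraically assigned.
#' @param model a `model_spec`
#' @return the model, invisibly
#' @export
validate_model_spec <- function(model) {
  states <- model$states
  assigned <- names(model$assignments)
  bad <- setdiff(assigned, states)
  if (length(bad))
    stop("algebraic assignment for unknown state: ", paste(bad, collapse = ", "),
         call. = FALSE)
  for (s in assigned) {
    syms <- expr_symbols(model$assignments[[s]], sprintf("assignment of %s", s))
    if (s %in% syms)
      stop(sprintf("assignment of state '%s' references itself", s), call. = FALSE)
  }
  # a state may not be consumed/produced by a reaction while assigned
  dyn <- dynamic_states(model)
  for (rx in model$reactions) {
    touched <- c(rx$substrates, rx$products)
    bad <- setdiff(touched, states)
    if (length(bad))
      stop(sprintf("reaction %s ('%s') references unknown state: %s",
                   rx$id, rx$text, paste(bad, collapse = ", ")), call. = FALSE)
    bad <- intersect(touched, assigned)
    if (length(bad))
      stop(sprintf("state '%s' is algebraically assigned but still appears in reaction %s; remove the reaction or the assignment",
                   bad[[1L]], rx$id), call. = FALSE)
  }
  # every symbol resolves
  free <- free_parameters(model)
  known <- c(states, names(model$inputs), names(model$fixed), free, .RESERVED)
  check <- function(text, where) {
    syms <- expr_symbols(text, where)
    bad <- setdiff(syms, known)
    if (length(bad))
      stop(sprintf("unresolved symbol '%s' in %s", bad[[1L]], where), call. = FALSE)
  }
  for (rx in model$reactions) check(rx$rate, sprintf("rate of reaction %s", rx$id))
  for (o in names(model$observables)) {
    syms <- expr_symbols(model$observables[[o]], sprintf("observable %s", o))
    bad <- setdiff(syms, known)
    if (length(bad))
      stop(sprintf("observable '%s' references unknown symbol '%s' (not a state, assigned state, parameter or input)",
                   o, bad[[1L]]), call. = FALSE)
  }
  for (s in assigned) check(model$assignments[[s]], sprintf("assignment of %s", s))
  for (nm in names(model$inputs)) {
    syms <- expr_symbols(model$inputs[[nm]], sprintf("input %s", nm))
    bad <- setdiff(syms, c(.RESERVED, names(model$fixed)))
    if (length(bad))
      stop(sprintf("input '%s' may only depend on t and fixed parameters; found '%s'",
                   nm, bad[[1L]]), call. = FALSE)
  }
  for (o in names(model$errors)) {
    v <- model$errors[[o]]
    if (is.numeric(v) && v <= 0)
      stop(sprintf("sigma for observable '%s' must be positive", o), call. = FALSE)
  }
  invisible(model)
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("<model_spec '%s'>\n", x$name))
  cat(sprintf("  dynamic states : %s\n", paste(dynamic_states(x), collapse = ", ")))
  if (length(x$assignments))
    cat(sprintf("  assigned states: %s\n",
                paste(sprintf("%s = %s", names(x$assignments),
                              unlist(x$assignments)), collapse = "; ")))
  for (rx in x$reactions) cat(sprintf("  %s: %s\n", rx$id, format_reaction(rx)))
  if (length(x$inputs))
    cat(sprintf("  inputs         : %s\n",
                paste(sprintf("%s = %s", names(x$inputs), unlist(x$inputs)),
                      collapse = "; ")))
  cat(sprintf("  observables    : %s\n",
              paste(sprintf("%s = %s", names(x$observables),
                            unlist(x$observables)), collapse = "; ")))
  cat(sprintf("  free parameters: %s\n", paste(free_parameters(x), collapse = ", ")))
  if (length(x$fixed))
    cat(sprintf("  fixed          : %s\n",
                paste(sprintf("%s = %g", names(x$fixed), x$fixed), collapse = ", ")))
  invisible(x)
}

#' Construct a parameter vector on the log10 scale
#'
#' @param values named numeric vector, values on the log10 scale.
#' @param model optional `model_spec`; if given, names are checked against the
#'   model's free-parameter set.
#' @return named numeric vector of class `parameter_vector`
#' @export
parameter_vector <- function(values, model = NULL) {
  stopifnot(is.numeric(values))
  if (length(values) == 0L) names(values) <- character()
  stopifnot(!is.null(names(values)))
  if (any(!is.finite(values)))
    stop("parameter values must be finite on the log10 scale", call. = FALSE)
  if (!is.null(model)) {
    free <- free_parameters(model)
    if (!setequal(names(values), free))
      stop(sprintf("parameter names {%s} do not match the model's free set {%s}",
                   paste(names(values), collapse = ","),
                   paste(free, collapse = ",")), call. = FALSE)
    values <- values[free]
  }
  structure(values, class = "parameter_vector")
}

#' Convert natural-scale parameter values to a log10 parameter vector
#' @export
as_log10_parameters <- function(values, model = NULL) {
  if (any(values <= 0))
    stop("natural-scale parameters must be positive for log10 estimation",
         call. = FALSE)
  parameter_vector(log10(values), model)
}
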