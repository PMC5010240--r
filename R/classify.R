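# Identifiability classification and reduction-scenario suggestion. A profile
# is classified by the trichotomy (identifiable / practically non-identifiable
# with an open direction / structurally non-identifiable); co-parameter paths
# along the non-identifiable tail are regressed on the scanned parameter to
# decide whether compensation occurs; the combination maps to one of the four
# reduction scenarios (+|), (-|), (+updown), (-updown) with a concrete action.

.UPDOWN <- "\u2195"  # vertical double arrow marking coupled co-parameters

#' Tolerances used by the classifier
#'
#' @param flat_tol co-parameter path slopes (log10/log10) below this are
#'   "flat"
#' @param coupled_tol slopes above this are "coupled"; in between is
#'   "ambiguous" and never auto-acted on
#' @param structural_frac a profile whose total variation stays below
#'   `structural_frac * chi2` over the whole scan (with no crossing) is
#'   structurally non-identifiable
#' @param tail_window log10 span of the trailing scan window used for slope
#'   estimation on practically non-identifiable profiles
#' @export
classifier_tolerances <- function(flat_tol = 0.05, coupled_tol = 0.1,
                                  structural_frac = 0.01, tail_window = 1.5) {
  list(flat_tol = flat_tol, coupled_tol = coupled_tol,
       structural_frac = structural_frac, tail_window = tail_window)
}

#' @keywords internal
direction_uncrossed <- function(profile, side) {
  !identical(profile$end_status[[side]], "crossed_threshold")
}

#' Classify a profiled parameter's identifiability
#'
#' Implements the trichotomy: identifiable (threshold crossed on both sides),
#' structurally non-identifiable (profile flat over the full scan), or
#' practically non-identifiable with the open direction recorded in the class
#' label. Profiles whose scans failed on both sides are inconclusive.
#'
#' @param profile a `pl_profile`
#' @param tolerances see [classifier_tolerances()]
#' @return object of class `identifiability_report`: `parameter`, `class`,
#'   `ci`
#' @export
classify_profile <- function(profile, tolerances = classifier_tolerances()) {
  tol <- utils::modifyList(classifier_tolerances(), tolerances)
  st <- profile$end_status
  chi2 <- profile$threshold - profile$objective
  if (all(st == "integration_failed")) {
    cls <- "inconclusive"
  } else {
    crossed_lo <- !direction_uncrossed(profile, "lower")
    crossed_up <- !direction_uncrossed(profile, "upper")
    total_var <- diff(range(profile$pl))
    if (!crossed_lo && !crossed_up && total_var < tol$structural_frac * chi2) {
      cls <- "structurally_NI"
    } else if (crossed_lo && crossed_up) {
      cls <- "identifiable"
    } else if (!crossed_lo && !crossed_up) {
      cls <- "practically_NI_both"
    } else if (!crossed_up) {
      cls <- "practically_NI_upper"
    } else {
      cls <- "practically_NI_lower"
    }
  }
  ci <- if (identical(cls, "inconclusive")) NULL
        else confidence_interval(profile)
  structure(list(parameter = profile$param, class = cls, ci = ci),
            class = "identifiability_report")
}

#' @export
print.identifiability_report <- function(x, ...) {
  cat(sprintf("%s: %s", x$parameter, x$class))
  if (!is.null(x$ci))
    cat(sprintf("  CI(log10) = [%.4g, %.4g]", x$ci$lower, x$ci$upper))
  cat("\n")
  invisible(x)
}

#' Analyse co-parameter coupling along a profile tail
#'
#' Least-squares slope of every re-optimised co-parameter path against the
#' scanned parameter over the flattened tail of the non-identifiable
#' direction (the full scan for structurally non-identifiable profiles).
#' Slopes within `flat_tol` of zero are labelled `flat`, beyond `coupled_tol`
#' `coupled`, otherwise `ambiguous`. Tails with fewer than 5 points are
#' flagged low-confidence.
#'
#' @param profile a `pl_profile`
#' @param direction `"upper"`, `"lower"` or `NULL` (auto: the direction whose
#'   scan did not cross the threshold; `upper` wins if both are open)
#' @param tolerances see [classifier_tolerances()]
#' @return object of class `coupling_report`: data.frame with `parameter`,
#'   `slope`, `label`, plus attributes `direction` and `low_confidence`
#' @export
analyze_coupling <- function(profile, direction = NULL,
                             tolerances = classifier_tolerances()) {
  tol <- utils::modifyList(classifier_tolerances(), tolerances)
  if (is.null(direction)) {
    direction <- if (direction_uncrossed(profile, "upper")) "upper"
                 else if (direction_uncrossed(profile, "lower")) "lower"
                 else stop("profile crossed the threshold on both sides; no non-identifiable tail to analyse",
                           call. = FALSE)
  }
  co_names <- setdiff(colnames(profile$path), profile$param)
  g <- profile$grid
  n <- length(g)
  # structural profiles are linear over the whole scan: use every point
  cls_structural <- direction_uncrossed(profile, "upper") &&
    direction_uncrossed(profile, "lower") &&
    diff(range(profile$pl)) <
      tol$structural_frac * (profile$threshold - profile$objective)
  if (cls_structural) {
    idx <- seq_len(n)
  } else if (direction == "upper") {
    idx <- which(g >= g[[n]] - tol$tail_window)
  } else {
    idx <- which(g <= g[[1L]] + tol$tail_window)
  }
  low_conf <- length(idx) < 5L
  slopes <- vapply(co_names, function(p) {
    y <- profile$path[idx, p]
    if (length(idx) < 2L) return(NA_real_)
    stats::cov(g[idx], y) / stats::var(g[idx])
  }, numeric(1L))
  label <- ifelse(abs(slopes) < tol$flat_tol, "flat",
                  ifelse(abs(slopes) > tol$coupled_tol, "coupled", "ambiguous"))
  out <- data.frame(parameter = co_names, slope = unname(slopes),
                    label = unname(label), stringsAsFactors = FALSE)
  structure(out, direction = direction, low_confidence = low_conf,
            scanned = profile$param,
            class = c("coupling_report", "data.frame"))
}

#' @keywords internal
reactions_with_parameter <- function(model, param) {
  hits <- vapply(model$reactions, function(rx) param %in% expr_symbols(rx$rate),
                 logical(1L))
  model$reactions[hits]
}

#' Pick the mechanistically downstream state among a parameter's reactions
#'
#' Heuristic for the algebraic-substitution proposal: among the states touched
#' by the reactions carrying the parameter, prefer one that is produced by a
#' reaction whose rate involves a coupled co-parameter; otherwise the first
#' touched dynamic state.
#' @keywords internal
downstream_state <- function(model, param, coupled) {
  rxs <- reactions_with_parameter(model, param)
  touched <- unique(unlist(lapply(rxs, function(rx)
    c(rx$products, rx$substrates))))
  touched <- intersect(touched, dynamic_states(model))
  if (!length(touched)) return(NA_character_)
  for (s in touched) {
    producers <- Filter(function(rx) s %in% rx$products, model$reactions)
    if (any(vapply(producers, function(rx)
      any(coupled %in% expr_symbols(rx$rate)), logical(1L))))
      return(s)
  }
  touched[[1L]]
}

#' Map an identifiability/coupling result to a reduction scenario
#'
#' The flow chart: a structural non-identifiability is resolved by fixing the
#' parameter. A practical non-identifiability combines its open direction
#' (+ or -) with whether any co-parameter compensates along the tail (coupled,
#' marked by the vertical arrow) into one of four scenarios:
#' \itemize{
#'   \item `(+|)` fast limit, no compensation: lump the states of the
#'     parameter's conversion reaction;
#'   \item `(-|)` slow limit, no compensation: remove the reaction;
#'   \item `(+` coupled `)`: replace the downstream state by an algebraic
#'     relation (advisory);
#'   \item `(-` coupled `)`: inspect trajectories along the profile; the
#'     typical limit is a pool state whose consumption is negligible
#'     (advisory).
#' }
#' Coupled-scenario suggestions are advisory and never applied automatically.
#'
#' @param ident an `identifiability_report`
#' @param coupling a `coupling_report` (may be NULL for structural class)
#' @param model the `model_spec` that was profiled
#' @return object of class `scenario_suggestion`
#' @export
suggest_scenario <- function(ident, coupling, model) {
  cls <- ident$class
  param <- ident$parameter
  if (identical(cls, "identifiable"))
    stop("parameter is identifiable; nothing to reduce", call. = FALSE)
  if (identical(cls, "inconclusive"))
    stop("profile is inconclusive; no suggestion possible", call. = FALSE)

  if (identical(cls, "structurally_NI")) {
    coupled <- if (is.null(coupling)) character()
               else coupling$parameter[coupling$label == "coupled"]
    return(structure(list(
      scenario = "structural", action = "fix_parameter", advisory = FALSE,
      parameter = param, coupled = coupled, states = character(),
      reaction_id = NA_character_,
      note = "structural non-identifiability: fix one parameter of the transformation group to an arbitrary value"),
      class = "scenario_suggestion"))
  }

  direction <- attr(coupling, "direction")
  if (is.null(direction))
    direction <- if (identical(cls, "practically_NI_lower")) "lower" else "upper"
  sign <- if (direction == "upper") "+" else "-"
  coupled <- coupling$parameter[coupling$label == "coupled"]
  is_coupled <- length(coupled) > 0L
  scenario <- sprintf("(%s%s)", sign, if (is_coupled) .UPDOWN else "|")

  rxs <- reactions_with_parameter(model, param)
  if (!length(rxs) && !is_coupled) {
    return(structure(list(
      scenario = scenario, action = "fix_parameter", advisory = FALSE,
      parameter = param, coupled = character(), states = character(),
      reaction_id = NA_character_,
      note = "parameter is attached to no reaction and uncoupled; fixing it is the only reduction (check the observation model)"),
      class = "scenario_suggestion"))
  }

  if (!is_coupled) {
    rx <- if (length(rxs)) rxs[[1L]] else NULL
    if (sign == "+") {
      states <- if (!is.null(rx)) c(rx$substrates, rx$products) else character()
      return(structure(list(
        scenario = scenario, action = "lump_states", advisory = FALSE,
        parameter = param, coupled = character(), states = states,
        reaction_id = if (!is.null(rx)) rx$id else NA_character_,
        note = sprintf("rate may be arbitrarily fast: lump the states %s",
                       paste(states, collapse = " and "))),
        class = "scenario_suggestion"))
    }
    return(structure(list(
      scenario = scenario, action = "remove_reaction", advisory = FALSE,
      parameter = param, coupled = character(),
      states = if (!is.null(rx)) c(rx$substrates, rx$products) else character(),
      reaction_id = if (!is.null(rx)) rx$id else NA_character_,
      note = "rate may be arbitrarily slow: remove the reaction"),
      class = "scenario_suggestion"))
  }

  if (sign == "+") {
    target <- downstream_state(model, param, coupled)
    return(structure(list(
      scenario = scenario, action = "substitute_algebraic", advisory = TRUE,
      parameter = param, coupled = coupled,
      states = if (is.na(target)) character() else target,
      reaction_id = NA_character_,
      note = sprintf("coupled fast limit: replace state %s by an algebraic relation to its driver (advisory; verify trajectories first)",
                     if (is.na(target)) "?" else target)),
      class = "scenario_suggestion"))
  }

  pool <- {
    subs <- unique(unlist(lapply(rxs, `[[`, "substrates")))
    intersect(subs, dynamic_states(model))
  }
  structure(list(
    scenario = scenario, action = "inspect_trajectories", advisory = TRUE,
    parameter = param, coupled = coupled,
    states = pool, reaction_id = NA_character_,
    note = sprintf("coupled slow limit: inspect trajectories along the profile; the typical reduction treats %s as a constant pool feeding its reaction (advisory)",
                   paste(pool, collapse = "/"))),
    class = "scenario_suggestion")
}

#' @export
print.scenario_suggestion <- function(x, ...) {
  cat(sprintf("<scenario %s for %s: %s%s>\n", x$scenario, x$parameter,
              x$action, if (x$advisory) " (advisory)" else ""))
  if (length(x$coupled))
    cat(sprintf("  coupled set: %s\n", paste(x$coupled, collapse = ", ")))
  cat(sprintf("  %s\n", x$note))
  invisible(x)
}

#' Simulate trajectories for parameter sets along a profile
#'
#' The inspection tool for coupled scenarios: picks `n_points` parameter sets
#' evenly spaced along the scan grid (always including both ends) and
#' simulates each, tagging the result with the scan value.
#'
#' @param model a `model_spec`
#' @param profile a `pl_profile`
#' @param times output times
#' @param n_points number of parameter sets (default 11)
#' @return list of entries `list(scan_value, trajectory)`; points whose
#'   integration failed carry `trajectory = NULL`
#' @export
trajectories_along_profile <- function(model, profile, times, n_points = 11L) {
  stopifnot(n_points >= 1L)
  n <- length(profile$grid)
  idx <- if (n_points == 1L) {
    which.min(abs(profile$grid - as.numeric(profile$theta_hat[[profile$param]])))
  } else unique(round(seq(1L, n, length.out = min(n_points, n))))
  lapply(idx, function(i) {
    params <- profile$theta_hat
    params[colnames(profile$path)] <- profile$path[i, ]
    traj <- tryCatch(simulate_model(model, params, times),
                     integration_error = function(e) NULL)
    list(scan_value = profile$grid[[i]], trajectory = traj)
  })
}
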