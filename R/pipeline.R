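# The iterative reduction pipeline: fit, profile every free parameter,
# classify, apply the first non-advisory suggestion, validate by LRT, repeat
# until every parameter of interest is identifiable or only advisory
# (coupled-scenario) suggestions remain. Coupled reductions are never applied
# automatically.

#' Pipeline run configuration
#'
#' @param alpha confidence level for thresholds and tests
#' @param n_starts multi-start count for each fit
#' @param bounds log10 fit bounds
#' @param seed integer seed for start generation
#' @param rtol,atol ODE solver tolerances
#' @param step_config profile step control, see [profile_step_config()]
#' @param tolerances classifier tolerances, see [classifier_tolerances()]
#' @param max_iterations reduction-iteration cap
#' @param out_dir optional output directory for reports
#' @return list of class `run_config`
#' @export
run_config <- function(alpha = 0.95, n_starts = 50L, bounds = c(-3, 3),
                       seed = 1L, rtol = 1e-8, atol = 1e-10,
                       step_config = profile_step_config(),
                       tolerances = classifier_tolerances(),
                       max_iterations = 10L, out_dir = NULL) {
  stopifnot(alpha > 0, alpha < 1, n_starts >= 1, rtol > 0, atol > 0,
            max_iterations >= 1)
  stopifnot(all(unlist(step_config) > 0), all(unlist(tolerances) > 0))
  structure(list(alpha = alpha, n_starts = as.integer(n_starts),
                 bounds = bounds, seed = as.integer(seed), rtol = rtol,
                 atol = atol, step_config = step_config,
                 tolerances = tolerances,
                 max_iterations = as.integer(max_iterations),
                 out_dir = out_dir),
            class = "run_config")
}

#' @keywords internal
with_solver_tolerances <- function(config, expr) {
  old <- options(plreduce.rtol = config$rtol, plreduce.atol = config$atol)
  on.exit(options(old), add = TRUE)
  force(expr)
}

#' One fit / profile-all / classify pass over a model
#'
#' @param model a `model_spec`
#' @param data a `pl_dataset`
#' @param config a [run_config()]
#' @return list with `fit`, `profiles`, `reports` (identifiability),
#'   `couplings`, `suggestions` (for the non-identifiable parameters)
#' @export
analyze_identifiability <- function(model, data, config = run_config()) {
  fit <- with_solver_tolerances(config,
    fit_model(model, data, n_starts = config$n_starts,
              bounds = config$bounds, seed = config$seed))
  profiles <- with_solver_tolerances(config,
    profile_all(model, data, fit, alpha = config$alpha,
                step_config = config$step_config))
  reports <- lapply(profiles, classify_profile, tolerances = config$tolerances)
  couplings <- list()
  suggestions <- list()
  for (p in names(profiles)) {
    cls <- reports[[p]]$class
    if (cls %in% c("identifiable", "inconclusive")) next
    cp <- tryCatch(analyze_coupling(profiles[[p]],
                                    tolerances = config$tolerances),
                   error = function(e) NULL)
    couplings[[p]] <- cp
    suggestions[[p]] <- tryCatch(suggest_scenario(reports[[p]], cp, model),
                                 error = function(e) NULL)
  }
  list(fit = fit, profiles = profiles, reports = reports,
       couplings = couplings, suggestions = suggestions)
}

#' Iterative profile-likelihood model reduction
#'
#' Runs the flow chart: fit, profile all free parameters, classify, apply the
#' first applicable non-advisory reduction (structural fixes at the current
#' estimate, lumping, reaction removal), validate it against the current
#' model with a likelihood-ratio test, and iterate. Stops successfully when
#' every free parameter is identifiable; stops with status
#' `advisory_suggestions` when only coupled-scenario (advisory) proposals
#' remain, and with `rejected` when the LRT rejects a reduction.
#'
#' @param model a `model_spec`
#' @param data a `pl_dataset`
#' @param config a [run_config()]
#' @param verbose print one structured line per decision
#' @return list of class `auto_reduce_result`: final `model`, `fit`,
#'   `reports`, `reductions` (one record per applied step), `status`, `log`
#' @export
auto_reduce <- function(model, data, config = run_config(), verbose = TRUE) {
  say <- function(...) if (verbose) message(sprintf(...))
  reductions <- list()
  log <- character()
  status <- NULL
  ana <- NULL
  for (iter in seq_len(config$max_iterations)) {
    ana <- analyze_identifiability(model, data, config)
    classes <- vapply(ana$reports, `[[`, "", "class")
    for (p in names(classes)) {
      line <- sprintf("iter %d: %s -> %s", iter, p, classes[[p]])
      log <- c(log, line)
      say("%s", line)
    }
    if (all(classes == "identifiable")) { status <- "all_identifiable"; break }
    if (any(classes == "inconclusive")) { status <- "inconclusive"; break }

    applicable <- Filter(function(s) !is.null(s) && !s$advisory,
                         ana$suggestions)
    if (!length(applicable)) {
      for (s in ana$suggestions) {
        if (is.null(s)) next
        line <- sprintf("iter %d: advisory %s for %s (coupled: %s); stopping for inspection",
                        iter, s$scenario, s$parameter,
                        paste(s$coupled, collapse = ","))
        log <- c(log, line)
        say("%s", line)
      }
      status <- "advisory_suggestions"
      break
    }
    sg <- applicable[[1L]]
    reduced <- if (identical(sg$action, "fix_parameter")) {
      apply_suggestion(model, sg,
                       value = 10^as.numeric(ana$fit$theta_hat[[sg$parameter]]))
    } else apply_suggestion(model, sg)
    reduced_fit <- fit_model(reduced, data, n_starts = config$n_starts,
                             bounds = config$bounds, seed = config$seed)
    lrt <- likelihood_ratio_test(ana$fit, reduced_fit, alpha = config$alpha)
    record <- list(iteration = iter, scenario = sg$scenario,
                   action = sg$action, parameter = sg$parameter,
                   reaction_id = sg$reaction_id, states = sg$states,
                   free_before = length(ana$fit$free),
                   free_after = length(reduced_fit$free),
                   D = lrt$D, delta_dof = lrt$delta_dof,
                   accepted = lrt$accepted, alpha = config$alpha)
    reductions <- c(reductions, list(record))
    line <- sprintf("iter %d: %s %s via %s | D=%.4g dof=%d -> %s",
                    iter, sg$scenario, sg$parameter, sg$action, lrt$D,
                    lrt$delta_dof, if (lrt$accepted) "accepted" else "REJECTED")
    log <- c(log, line)
    say("%s", line)
    if (!lrt$accepted) { status <- "rejected"; break }
    model <- reduced
    ana$fit <- reduced_fit
  }
  if (is.null(status)) status <- "iteration_limit"
  structure(list(model = model, fit = ana$fit, reports = ana$reports,
                 profiles = ana$profiles, suggestions = ana$suggestions,
                 reductions = reductions, status = status, log = log),
            class = "auto_reduce_result")
}

#' @export
print.auto_reduce_result <- function(x, ...) {
  cat(sprintf("<auto_reduce: status %s after %d reduction(s)>\n", x$status,
              length(x$reductions)))
  for (r in x$reductions)
    cat(sprintf("  iter %d: %s on %s (D = %.4g, dof %d, %s)\n", r$iteration,
                r$action, r$parameter, r$D, r$delta_dof,
                if (r$accepted) "accepted" else "rejected"))
  cat(sprintf("  free parameters: %s\n", paste(x$fit$free, collapse = ", ")))
  invisible(x)
}
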