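# Numerical integration of compiled models with deSolve (lsoda, stiff-capable;
# default rtol 1e-8, atol 1e-10) and evaluation of the observation map.
# Failures are raised as 'integration_error' conditions carrying the parameter
# point so that optimiser and profiler can mark the point instead of aborting.

.DEFAULT_RTOL <- function() getOption("plreduce.rtol", 1e-8)
.DEFAULT_ATOL <- function() getOption("plreduce.atol", 1e-10)

#' @keywords internal
integration_error <- function(message, params = NULL) {
  structure(class = c("integration_error", "error", "condition"),
            list(message = message, call = NULL, params = params))
}

#' @keywords internal
check_times <- function(times) {
  if (length(times) < 1L || any(diff(times) <= 0) || times[[1L]] < 0)
    stop("times must be strictly increasing and start at >= 0", call. = FALSE)
}

#' @keywords internal
theta_natural <- function(model, params, cmp = compile_model(model)) {
  missing <- setdiff(cmp$theta, names(params))
  if (length(missing))
    stop("missing parameter value(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  p <- 10^as.numeric(params[cmp$theta])
  names(p) <- cmp$theta
  p
}

#' @keywords internal
run_ode <- function(cmp, what = c("f", "fs"), y0, times, parms, rtol, atol) {
  what <- match.arg(what)
  t0 <- if (times[[1L]] > 0) c(0, times) else times
  out <- tryCatch(suppressWarnings({
    if (!is.null(cmp$cback)) {
      deSolve::ode(y = y0, times = t0, func = cmp$cback[[what]], parms = parms,
                   dllname = cmp$cback$dllname, initfunc = cmp$cback$init,
                   method = "lsoda", rtol = rtol, atol = atol)
    } else {
      fn <- if (what == "f") cmp$f_fun else cmp$fs_fun
      deSolve::ode(y = y0, times = t0, func = fn, parms = parms,
                   method = "lsoda", rtol = rtol, atol = atol)
    }
  }), error = function(e) NULL)
  ok <- !is.null(out) && nrow(out) == length(t0) && !anyNA(out) &&
    all(is.finite(out))
  if (!ok)
    stop(integration_error("ODE integration failed (stiffness or blow-up)",
                           params = parms))
  if (times[[1L]] > 0) out <- out[-1L, , drop = FALSE]
  out
}

#' Simulate a model
#'
#' Solves the assembled ODE system from the model's initial conditions.
#'
#' @param model a `model_spec`
#' @param params named log10-scale parameter vector covering the free set
#' @param times strictly increasing output times, `times[1] >= 0`
#' @param rtol,atol solver tolerances
#' @return an object of class `trajectory`: list with `times` and `states`
#'   (time x state matrix including algebraically assigned states)
#' @export
simulate_model <- function(model, params, times,
                           rtol = .DEFAULT_RTOL(), atol = .DEFAULT_ATOL(),
                           cmp = compile_model(model)) {
  check_times(times)
  th <- theta_natural(model, params, cmp)
  out <- run_ode(cmp, "f", cmp$x0_fun(th), times, th, rtol, atol)
  xmat <- out[, 1L + seq_len(cmp$nx), drop = FALSE]
  colnames(xmat) <- cmp$dyn
  amat <- cmp$assigned_fun(times, xmat, th)
  if (!is.null(amat)) xmat <- cbind(xmat, amat)
  structure(list(times = times, states = xmat,
                 assigned = names(model$assignments)),
            class = "trajectory")
}

#' Simulate a model together with forward sensitivities
#'
#' Integrates the ODE system extended with the forward sensitivity equations.
#' Sensitivities are with respect to the log10-scale parameters
#' (`dx/dlog10 theta = theta * ln(10) * dx/dtheta`); at `t = 0` the
#' sensitivity of a state to a free initial condition equals `x0 * ln(10)`
#' and all kinetic-parameter sensitivities vanish.
#'
#' @inheritParams simulate_model
#' @return list with elements `trajectory` (class `trajectory`, dynamic
#'   states only in `sens`) and `sens` (array time x state x parameter)
#' @export
simulate_sensitivities <- function(model, params, times,
                                   rtol = .DEFAULT_RTOL(), atol = .DEFAULT_ATOL(),
                                   cmp = compile_model(model)) {
  check_times(times)
  th <- theta_natural(model, params, cmp)
  y0 <- c(cmp$x0_fun(th), as.numeric(cmp$s0_fun(th)))
  out <- run_ode(cmp, "fs", y0, times, th, rtol, atol)
  nt <- length(times)
  xmat <- out[, 1L + seq_len(cmp$nx), drop = FALSE]
  colnames(xmat) <- cmp$dyn
  sens <- array(out[, 1L + cmp$nx + seq_len(cmp$nx * cmp$np)],
                c(nt, cmp$nx, cmp$np),
                dimnames = list(NULL, cmp$dyn, cmp$theta))
  amat <- cmp$assigned_fun(times, xmat, th)
  smat <- if (!is.null(amat)) cbind(xmat, amat) else xmat
  traj <- structure(list(times = times, states = smat,
                         assigned = names(model$assignments)),
                    class = "trajectory")
  list(trajectory = traj, sens = sens)
}

#' Evaluate the observation map on a trajectory
#'
#' Applies each observable expression pointwise to the trajectory; no noise is
#' added.
#' @param model a `model_spec`
#' @param trajectory a `trajectory` from [simulate_model()]
#' @param params named log10-scale parameter vector (supplies observational
#'   parameters)
#' @return matrix time x observable
#' @export
observe_model <- function(model, trajectory, params) {
  cmp <- compile_model(model)
  th <- theta_natural(model, params, cmp)
  xmat <- trajectory$states[, cmp$dyn, drop = FALSE]
  cmp$obs_fun(trajectory$times, xmat, th)
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory: %d time points, states %s>\n", length(x$times),
              paste(colnames(x$states), collapse = ", ")))
  invisible(x)
}
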