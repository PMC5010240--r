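# Maximum-likelihood estimation: deterministic multi-start trust-region least
# squares (minpack.lm::nls.lm) with analytic Jacobians from the forward
# sensitivities. Starts are Latin-hypercube samples in the log10 bounds,
# reproducible for a fixed seed.

.DEFAULT_BOUNDS <- c(-3, 3)
.TIE_TOL <- 1e-8

#' @keywords internal
expand_bounds <- function(bounds, free) {
  if (is.numeric(bounds) && length(bounds) == 2L && is.null(names(bounds))) {
    lower <- rep(bounds[[1L]], length(free))
    upper <- rep(bounds[[2L]], length(free))
  } else if (is.list(bounds)) {
    lower <- rep(.DEFAULT_BOUNDS[[1L]], length(free))
    upper <- rep(.DEFAULT_BOUNDS[[2L]], length(free))
    for (i in seq_along(free)) {
      b <- bounds[[free[[i]]]]
      if (!is.null(b)) { lower[[i]] <- b[[1L]]; upper[[i]] <- b[[2L]] }
    }
  } else stop("bounds must be c(lower, upper) or a named list", call. = FALSE)
  if (any(!is.finite(lower)) || any(!is.finite(upper)) || any(lower >= upper))
    stop("bounds must be finite with lower < upper (log10 scale)", call. = FALSE)
  names(lower) <- names(upper) <- free
  list(lower = lower, upper = upper)
}

#' Latin-hypercube start matrix in the log10 bounds (deterministic per seed)
#' @keywords internal
lhs_starts <- function(n_starts, lower, upper, seed) {
  k <- length(lower)
  set.seed(seed)
  u <- lhs::randomLHS(n_starts, max(k, 1L))
  starts <- sweep(sweep(u[, seq_len(k), drop = FALSE], 2L, upper - lower, "*"),
                  2L, lower, "+")
  colnames(starts) <- names(lower)
  starts
}

#' Single local trust-region least-squares fit
#' @keywords internal
local_fit <- function(model, data, start, fixed, lower, upper, prior, control,
                      cmp = compile_model(model)) {
  free <- names(start)
  cache <- new.env(parent = emptyenv())
  evaluate <- function(p) {
    if (!is.null(cache$p) && identical(cache$p, p)) return(cache$rj)
    full <- c(p, fixed)
    rj <- residuals_and_jacobian(model, data, full, prior, cmp = cmp)
    cache$p <- p
    cache$rj <- rj
    rj
  }
  fn <- function(p) { names(p) <- free; evaluate(p)$residuals }
  jac <- function(p) {
    names(p) <- free
    evaluate(p)$jacobian[, free, drop = FALSE]
  }
  ctrl <- do.call(minpack.lm::nls.lm.control,
                  utils::modifyList(list(maxiter = 150, ftol = 1e-13,
                                         ptol = 1e-11, gtol = 0), control))
  ans <- tryCatch(
    minpack.lm::nls.lm(par = start, lower = lower, upper = upper,
                       fn = fn, jac = jac, control = ctrl),
    error = function(e) e)
  if (inherits(ans, "error"))
    return(list(ok = FALSE, message = conditionMessage(ans)))
  par <- ans$par
  names(par) <- free
  list(ok = TRUE, par = par, objective = ans$deviance,
       converged = ans$info %in% 1:4, info = ans$info,
       message = ans$message)
}

#' Fit a model by deterministic multi-start maximum likelihood
#'
#' Draws `n_starts` Latin-hypercube starting points in the log10 bounds and
#' runs a trust-region least-squares fit (analytic Jacobian via forward
#' sensitivities) from each. The best final objective wins; among objectives
#' within `1e-8` of each other the lexicographically smallest parameter vector
#' is kept, for reproducibility.
#'
#' @param model a `model_spec`
#' @param data a `pl_dataset`
#' @param n_starts number of starts (>= 1)
#' @param bounds `c(lower, upper)` in log10 units applied to every free
#'   parameter, or a named list of per-parameter bounds
#' @param seed integer seed controlling start generation
#' @param fixed optional named log10-scale values of parameters to hold fixed
#'   during this fit (used by the profiler)
#' @param starts optional matrix of explicit log10 starts (rows = starts);
#'   overrides Latin-hypercube generation
#' @param prior optional quadratic prior (list with `mean`, `sd`, log10 scale)
#' @param control passed to [minpack.lm::nls.lm.control()]
#' @return object of class `fit_result`: `theta_hat` (log10), `objective`,
#'   `multistart` table, `bounds`, `seed`, `fixed`, `free`
#' @export
fit_model <- function(model, data, n_starts = 50L, bounds = .DEFAULT_BOUNDS,
                      seed = 1L, fixed = NULL, starts = NULL, prior = NULL,
                      control = list()) {
  stopifnot(n_starts >= 1L)
  data <- dataset(data, model)
  all_free <- free_parameters(model)
  if (!is.null(fixed)) {
    bad <- setdiff(names(fixed), all_free)
    if (length(bad))
      stop("fixed refers to unknown parameter(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
  }
  free <- setdiff(all_free, names(fixed))
  fixed <- if (is.null(fixed)) numeric() else unlist(fixed)

  if (length(sigma_parameters(model)) && any(sigma_parameters(model) %in% free))
    return(fit_model_general(model, data, n_starts, bounds, seed, fixed,
                             starts, prior))

  if (length(free) == 0L) {
    obj <- neg2_log_likelihood(model, data, fixed, prior)
    return(structure(list(
      theta_hat = parameter_vector(fixed[all_free]),
      objective = as.numeric(obj),
      multistart = data.frame(start = 1L, objective = as.numeric(obj),
                              converged = TRUE),
      bounds = NULL, seed = seed, fixed = fixed, free = character()),
      class = "fit_result"))
  }

  b <- expand_bounds(bounds, free)
  if (is.null(starts)) {
    starts <- lhs_starts(n_starts, b$lower, b$upper, seed)
  } else {
    starts <- matrix(as.numeric(starts), ncol = length(free),
                     dimnames = list(NULL, free))
    starts[] <- pmin(pmax(starts, rep(b$lower, each = nrow(starts))),
                     rep(b$upper, each = nrow(starts)))
  }

  cmp <- compile_model(model)
  results <- vector("list", nrow(starts))
  for (i in seq_len(nrow(starts))) {
    st <- starts[i, ]
    names(st) <- free
    results[[i]] <- local_fit(model, data, st, fixed, b$lower, b$upper,
                              prior, control, cmp = cmp)
  }
  ok <- vapply(results, `[[`, TRUE, "ok")
  if (!any(ok)) {
    msgs <- vapply(results, function(r) r$message %||% "", character(1L))
    stop("all optimisation starts failed:\n",
         paste(sprintf("  start %d: %s", seq_along(msgs), msgs), collapse = "\n"),
         call. = FALSE)
  }
  objs <- vapply(results, function(r) if (isTRUE(r$ok)) r$objective else Inf,
                 numeric(1L))
  best_obj <- min(objs)
  cand <- which(objs <= best_obj + .TIE_TOL)
  if (length(cand) > 1L) {
    mats <- do.call(rbind, lapply(results[cand], `[[`, "par"))
    ord <- do.call(order, as.data.frame(mats))
    best <- cand[[ord[[1L]]]]
  } else best <- cand[[1L]]

  theta_free <- results[[best]]$par
  theta_all <- c(theta_free, fixed)[all_free]
  ms <- data.frame(
    start = seq_len(nrow(starts)),
    objective = objs,
    converged = vapply(results, function(r) isTRUE(r$ok) && isTRUE(r$converged),
                       logical(1L)))
  ms <- ms[order(ms$objective), ]
  structure(list(
    theta_hat = parameter_vector(theta_all),
    objective = results[[best]]$objective,
    multistart = ms,
    bounds = b, seed = seed, fixed = fixed, free = free),
    class = "fit_result")
}

#' General-objective fallback when sigma parameters are estimated
#' @keywords internal
fit_model_general <- function(model, data, n_starts, bounds, seed, fixed,
                              starts, prior) {
  all_free <- free_parameters(model)
  free <- setdiff(all_free, names(fixed))
  b <- expand_bounds(bounds, free)
  if (is.null(starts)) starts <- lhs_starts(n_starts, b$lower, b$upper, seed)
  obj_fun <- function(p) {
    names(p) <- free
    as.numeric(neg2_log_likelihood(model, data, c(p, fixed), prior))
  }
  best <- NULL
  objs <- rep(NA_real_, nrow(starts))
  conv <- logical(nrow(starts))
  for (i in seq_len(nrow(starts))) {
    st <- starts[i, ]
    names(st) <- free
    ans <- tryCatch(stats::optim(st, obj_fun, method = "L-BFGS-B",
                                 lower = b$lower, upper = b$upper,
                                 control = list(maxit = 500, factr = 1e4)),
                    error = function(e) NULL)
    if (is.null(ans)) next
    objs[[i]] <- ans$value
    conv[[i]] <- ans$convergence == 0
    if (is.null(best) || ans$value < best$value) best <- ans
  }
  if (is.null(best)) stop("all optimisation starts failed", call. = FALSE)
  theta_all <- c(best$par, fixed)[all_free]
  ms <- data.frame(start = seq_len(nrow(starts)), objective = objs,
                   converged = conv)
  ms <- ms[order(ms$objective), ]
  structure(list(theta_hat = parameter_vector(theta_all),
                 objective = best$value, multistart = ms, bounds = b,
                 seed = seed, fixed = fixed, free = free),
            class = "fit_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result: objective %.6g, %d start(s)>\n", x$objective,
              nrow(x$multistart)))
  nat <- 10^as.numeric(x$theta_hat)
  for (i in seq_along(x$theta_hat))
    cat(sprintf("  %-12s log10 = %8.4f   natural = %.6g%s\n",
                names(x$theta_hat)[[i]], as.numeric(x$theta_hat)[[i]], nat[[i]],
                if (names(x$theta_hat)[[i]] %in% names(x$fixed)) " (fixed)" else ""))
  invisible(x)
}
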