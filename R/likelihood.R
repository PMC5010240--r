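# The -2 log L objective for additive Gaussian measurement errors, and its
# weighted-residual / analytic-Jacobian form used by the trust-region
# optimiser. Residuals are (y - g)/sigma; the Jacobian is propagated through
# the observation map and the forward sensitivities, in log10 parameter units.

.FAIL_OBJECTIVE <- 1e10

#' Construct a measurement dataset
#'
#' @param records data.frame with columns `observable`, `time`, `value`,
#'   `sigma` (per-point standard deviation, must be positive where used).
#' @param model optional `model_spec` for observable-name validation.
#' @return data.frame of class `pl_dataset`
#' @export
dataset <- function(records, model = NULL) {
  need <- c("observable", "time", "value", "sigma")
  missing <- setdiff(need, names(records))
  if (length(missing))
    stop("dataset is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  records <- as.data.frame(records)[need]
  if (nrow(records) < 1L) stop("dataset must contain at least one record",
                               call. = FALSE)
  records$observable <- as.character(records$observable)
  for (col in c("time", "value", "sigma")) {
    if (!is.numeric(records[[col]]))
      stop(sprintf("dataset column '%s' must be numeric", col), call. = FALSE)
  }
  bad <- which(!is.na(records$sigma) & records$sigma <= 0)
  if (length(bad))
    stop(sprintf("non-positive sigma in dataset row %d", bad[[1L]]), call. = FALSE)
  if (!is.null(model)) {
    bad <- setdiff(unique(records$observable), names(model$observables))
    if (length(bad))
      stop("dataset references unknown observable(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
  }
  class(records) <- c("pl_dataset", "data.frame")
  records
}

#' Per-record sigma values given the model's error specification
#'
#' Numeric error entries override the dataset column; `"data"` uses the
#' per-point sigma; a parameter name draws sigma from `theta_nat`.
#' @keywords internal
record_sigmas <- function(model, data, theta_nat) {
  sig <- numeric(nrow(data))
  is_free <- logical(nrow(data))
  for (o in unique(data$observable)) {
    rows <- data$observable == o
    spec <- model$errors[[o]]
    if (is.null(spec)) spec <- "data"
    if (is.numeric(spec)) {
      sig[rows] <- spec
    } else if (identical(spec, "data")) {
      s <- data$sigma[rows]
      if (anyNA(s)) stop(sprintf(
        "observable '%s' uses per-datapoint sigma but the dataset has NA sigma",
        o), call. = FALSE)
      sig[rows] <- s
    } else {
      sig[rows] <- theta_nat[[spec]]
      is_free[rows] <- TRUE
    }
  }
  list(sigma = sig, free = is_free)
}

#' @keywords internal
predict_records <- function(model, data, params, sens = FALSE,
                            cmp = compile_model(model)) {
  times <- sort(unique(data$time))
  if (sens) {
    sim <- simulate_sensitivities(model, params, times, cmp = cmp)
    traj <- sim$trajectory
  } else {
    traj <- simulate_model(model, params, times, cmp = cmp)
    sim <- NULL
  }
  th <- theta_natural(model, params, cmp)
  xmat <- traj$states[, cmp$dyn, drop = FALSE]
  g <- cmp$obs_fun(times, xmat, th)
  ti <- match(data$time, times)
  oi <- match(data$observable, colnames(g))
  pred <- g[cbind(ti, oi)]
  out <- list(pred = pred, times = times, ti = ti, oi = oi, theta = th, cmp = cmp)
  if (sens) {
    gj <- cmp$obs_jac_fun(times, xmat, sim$sens, th)
    jac <- matrix(NA_real_, nrow(data), cmp$np, dimnames = list(NULL, cmp$theta))
    for (k in seq_len(cmp$np)) {
      gk <- matrix(gj[, , k], nrow = length(times))
      jac[, k] <- gk[cbind(ti, oi)]
    }
    out$pred_jac <- jac
  }
  out
}

#' @keywords internal
prior_terms <- function(prior, params) {
  if (is.null(prior)) return(NULL)
  stopifnot(is.list(prior), !is.null(prior$mean), !is.null(prior$sd))
  nm <- names(prior$mean)
  list(names = nm,
       res = (as.numeric(params[nm]) - as.numeric(prior$mean)) /
         as.numeric(prior$sd),
       w = 1 / as.numeric(prior$sd))
}

#' Evaluate -2 log L
#'
#' Computes `sum(((y_i - g_i)/sigma_i)^2)`; when a sigma is a free parameter
#' the Gaussian normalisation `sum(log sigma_i^2)` over the affected points is
#' added. Optional quadratic prior penalties on log10 parameters are added.
#' Integration failures return the large finite sentinel `1e10` with attribute
#' `failed = TRUE` so optimiser and profiler can retreat instead of aborting.
#'
#' @param model a `model_spec`
#' @param data a `pl_dataset`
#' @param params named log10-scale parameter vector
#' @param prior optional list with named numeric `mean` and `sd` (log10 scale)
#' @return scalar objective value
#' @export
neg2_log_likelihood <- function(model, data, params, prior = NULL,
                                cmp = compile_model(model)) {
  pr <- tryCatch(predict_records(model, data, params, cmp = cmp),
                 integration_error = function(e) NULL)
  if (is.null(pr))
    return(structure(.FAIL_OBJECTIVE, failed = TRUE))
  sg <- record_sigmas(model, data, pr$theta)
  value <- sum(((data$value - pr$pred) / sg$sigma)^2)
  if (any(sg$free)) value <- value + sum(log(sg$sigma[sg$free]^2))
  pt <- prior_terms(prior, params)
  if (!is.null(pt)) value <- value + sum(pt$res^2)
  value
}

#' Weighted residuals and analytic Jacobian
#'
#' Residuals `(y_i - g_i)/sigma_i` and their derivative matrix with respect to
#' the log10-scale parameters (via the observation map and the forward
#' sensitivities). `sum(residuals^2)` equals [neg2_log_likelihood()] in the
#' fixed-sigma case. Prior penalties contribute extra rows.
#'
#' @inheritParams neg2_log_likelihood
#' @return list with `residuals`, `jacobian` (rows = records + prior rows,
#'   columns = free parameters) and `failed`
#' @export
residuals_and_jacobian <- function(model, data, params, prior = NULL,
                                   cmp = compile_model(model)) {
  n <- nrow(data)
  pt <- prior_terms(prior, params)
  npr <- if (is.null(pt)) 0L else length(pt$res)
  pr <- tryCatch(predict_records(model, data, params, sens = TRUE, cmp = cmp),
                 integration_error = function(e) NULL)
  if (is.null(pr)) {
    res <- rep(sqrt(.FAIL_OBJECTIVE / (n + npr)), n + npr)
    jac <- matrix(0, n + npr, cmp$np, dimnames = list(NULL, cmp$theta))
    return(list(residuals = res, jacobian = jac, failed = TRUE))
  }
  sg <- record_sigmas(model, data, pr$theta)
  if (any(sg$free))
    stop("residuals_and_jacobian requires fixed sigmas; use the general objective for free sigma parameters",
         call. = FALSE)
  res <- (data$value - pr$pred) / sg$sigma
  jac <- -pr$pred_jac / sg$sigma
  if (!is.null(pt)) {
    res <- c(res, pt$res)
    jrows <- matrix(0, npr, cmp$np, dimnames = list(NULL, cmp$theta))
    for (i in seq_len(npr)) jrows[i, pt$names[[i]]] <- pt$w[[i]]
    jac <- rbind(jac, jrows)
  }
  list(residuals = res, jacobian = jac, failed = FALSE)
}
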