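# Profile likelihood: scan one parameter away from its estimate in both
# directions, re-optimising all other parameters at every grid point (warm
# start from the previous point's optimum), with adaptive step control
# targeting a fixed likelihood increment per step. Confidence intervals come
# from the chi-square threshold crossing, refined by regula falsi.

#' Chi-square threshold for profile-likelihood confidence regions
#'
#' @param alpha confidence level in (0, 1)
#' @param dof degrees of freedom (>= 1); 1 for pointwise parameter profiles
#' @return the alpha quantile of the chi-square distribution
#' @export
chi2_threshold <- function(alpha, dof = 1L) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    stop("alpha must lie strictly between 0 and 1", call. = FALSE)
  if (dof < 1L) stop("dof must be >= 1", call. = FALSE)
  stats::qchisq(alpha, df = dof)
}

#' Default step-control configuration for profile scans
#'
#' Steps are in log10 units, adapted to a target likelihood increment of
#' `chi2_threshold(alpha)/50` per step: halved when a step overshoots twice
#' the target, grown 1.5x when it undershoots a fifth of it.
#' @export
profile_step_config <- function(target_frac = 1 / 50, init_step = 0.01,
                                min_step = 1e-3, max_step = 0.5,
                                scan_range = 5, max_steps = 500L,
                                overshoot = 1.0, flat_window = 1.0,
                                flat_tol_frac = 0.01) {
  list(target_frac = target_frac, init_step = init_step, min_step = min_step,
       max_step = max_step, scan_range = scan_range, max_steps = max_steps,
       overshoot = overshoot, flat_window = flat_window,
       flat_tol_frac = flat_tol_frac)
}

#' Re-optimise nuisance parameters with the scanned parameter fixed
#' @return list(ok, pl, co) where co is the named co-parameter vector
#' @keywords internal
reopt_point <- function(model, data, co_start, fixed_all, lower, upper, prior,
                        cmp) {
  if (length(co_start) == 0L) {
    obj <- neg2_log_likelihood(model, data, fixed_all, prior, cmp = cmp)
    if (isTRUE(attr(obj, "failed"))) return(list(ok = FALSE))
    return(list(ok = TRUE, pl = as.numeric(obj), co = numeric()))
  }
  ans <- local_fit(model, data, co_start, fixed_all, lower, upper, prior,
                   list(), cmp = cmp)
  if (!isTRUE(ans$ok) || !is.finite(ans$objective) ||
      ans$objective >= .FAIL_OBJECTIVE / 2)
    return(list(ok = FALSE))
  list(ok = TRUE, pl = ans$objective, co = ans$par)
}

#' @keywords internal
scan_direction <- function(model, data, param, dir, center_val, center_pl,
                           center_co, fixed, lower, upper, prior, cfg, chi2,
                           objective, cmp) {
  target <- chi2 * cfg$target_frac
  threshold <- objective + chi2
  step <- cfg$init_step
  cur_val <- center_val
  cur_pl <- center_pl
  cur_co <- center_co
  vals <- numeric()
  pls <- numeric()
  cos <- list()
  consec_fail <- 0L
  n_steps <- 0L
  status <- NULL
  refined <- NA_real_
  crossed <- FALSE  # exceeded threshold + overshoot at least once
  limit <- center_val + dir * cfg$scan_range

  while (is.null(status)) {
    n_steps <- n_steps + 1L
    if (n_steps > cfg$max_steps) { status <- "hit_max_steps"; break }
    at_limit <- FALSE
    prop <- cur_val + dir * step
    if ((dir > 0 && prop >= limit) || (dir < 0 && prop <= limit)) {
      prop <- limit
      at_limit <- TRUE
    }
    res <- reopt_point(model, data, cur_co, c(fixed, stats::setNames(prop, param)),
                       lower, upper, prior, cmp)
    if (!res$ok) {
      consec_fail <- consec_fail + 1L
      if (consec_fail > 10L) { status <- "integration_failed"; break }
      step <- max(step / 2, cfg$min_step)
      next
    }
    dpl <- res$pl - cur_pl
    if (!crossed && dpl > 2 * target && step > cfg$min_step && !at_limit) {
      step <- max(step / 2, cfg$min_step)
      next
    }
    # accept
    consec_fail <- 0L
    vals <- c(vals, prop)
    pls <- c(pls, res$pl)
    cos <- c(cos, list(res$co))
    if (!crossed && res$pl - objective > chi2 + cfg$overshoot) {
      # the confidence region may resume beyond this barrier: coast on at
      # the step cap to the scan limit and judge the direction from the tail
      crossed <- TRUE
      step <- cfg$max_step
    }
    if (at_limit) { status <- "at_limit"; break }
    if (!crossed && abs(dpl) < 0.2 * target)
      step <- min(step * 1.5, cfg$max_step)
    cur_val <- prop
    cur_pl <- res$pl
    cur_co <- res$co
  }

  # resolve the end status from the whole curve: an open tail (back below the
  # threshold at the scan limit) outranks an interior barrier crossing
  tail_open <- length(pls) > 0 && utils::tail(pls, 1L) <= threshold
  if (identical(status, "at_limit")) {
    status <- if (tail_open &&
                  is_flat_tail(c(center_val, vals), c(center_pl, pls), dir,
                               cfg$flat_window, cfg$flat_tol_frac * chi2))
      "flattened"
    else if (tail_open) "hit_scan_limit"
    else "crossed_threshold"
  } else if (crossed && !tail_open &&
             status %in% c("hit_max_steps", "integration_failed")) {
    status <- "crossed_threshold"
  }

  # refine the first threshold crossing (the confidence-interval endpoint)
  allp <- c(center_pl, pls)
  if (any(allp > threshold)) {
    allv <- c(center_val, vals)
    j <- min(which(allp > threshold))
    if (j > 1L) {
      refined <- refine_crossing(model, data, param,
                                 allv[[j - 1L]], allp[[j - 1L]],
                                 allv[[j]], allp[[j]],
                                 if (j == 2L) center_co else cos[[j - 2L]],
                                 threshold, fixed, lower, upper, prior, cmp)
    }
  }

  list(vals = vals, pls = pls, cos = cos, status = status, refined = refined)
}

#' Flatness rule: trailing window of >= flat_window log10 units with total PL
#' variation below tol
#' @keywords internal
is_flat_tail <- function(vals, pls, dir, flat_window, tol) {
  n <- length(vals)
  if (n < 2L) return(FALSE)
  span <- abs(vals[n] - vals)
  in_win <- span <= flat_window
  # the scan must actually cover flat_window units
  if (max(span) < flat_window) return(FALSE)
  # include the nearest point outside the window so it is fully covered
  idx <- c(max(which(!in_win)), which(in_win))
  diff(range(pls[idx])) < tol
}

#' Regula-falsi refinement of the PL = threshold crossing
#' @keywords internal
refine_crossing <- function(model, data, param, v_lo, pl_lo, v_hi, pl_hi,
                            co_warm, threshold, fixed, lower, upper, prior,
                            cmp, max_iter = 40L, tol = 1e-10) {
  f_lo <- pl_lo - threshold
  f_hi <- pl_hi - threshold
  if (f_lo * f_hi > 0) return(NA_real_)
  co <- co_warm
  v_mid <- NA_real_
  for (i in seq_len(max_iter)) {
    v_mid <- v_lo + (v_hi - v_lo) * (-f_lo) / (f_hi - f_lo)
    if (!is.finite(v_mid)) break
    res <- reopt_point(model, data, co,
                       c(fixed, stats::setNames(v_mid, param)),
                       lower, upper, prior, cmp)
    if (!res$ok) break
    f_mid <- res$pl - threshold
    if (length(res$co)) co <- res$co
    if (abs(f_mid) < tol || abs(v_hi - v_lo) < 1e-12) return(v_mid)
    if (f_lo * f_mid <= 0) { v_hi <- v_mid; f_hi <- f_mid }
    else { v_lo <- v_mid; f_lo <- f_mid }
  }
  v_mid
}

#' Compute the profile likelihood of one parameter
#'
#' Scans bidirectionally from the estimate, re-optimising all other free
#' parameters at each grid point starting from the previous point's optimum.
#' A direction ends when the profile exceeds the chi-square threshold by the
#' overshoot margin (so the crossing is bracketed), when the scan limit is
#' reached (resolved to `flattened` or `hit_scan_limit` by the flatness rule),
#' when the step budget is exhausted, or after more than 10 consecutive
#' re-optimisation failures. Nuisance-parameter bounds are the fit bounds
#' widened by the scan range, so compensating parameters can follow the scan.
#'
#' @param model a `model_spec`
#' @param data a `pl_dataset`
#' @param fit a `fit_result` from [fit_model()]
#' @param param name of the free parameter to profile
#' @param alpha confidence level for the stopping threshold (dof 1)
#' @param step_config see [profile_step_config()]
#' @param prior optional prior passed through to the objective
#' @return object of class `pl_profile` with the scan grid (log10), PL values,
#'   co-parameter path matrix, threshold, per-direction end statuses and
#'   refined interval endpoints
#' @export
profile_likelihood <- function(model, data, fit, param, alpha = 0.95,
                               step_config = profile_step_config(),
                               prior = NULL) {
  stopifnot(inherits(fit, "fit_result"))
  if (!param %in% fit$free)
    stop(sprintf("parameter '%s' is not free in this fit", param), call. = FALSE)
  cfg <- utils::modifyList(profile_step_config(), step_config)
  cmp <- compile_model(model)
  chi2 <- chi2_threshold(alpha, 1L)
  data <- dataset(data, model)

  co_names <- setdiff(fit$free, param)
  center_val <- as.numeric(fit$theta_hat[[param]])
  center_co <- stats::setNames(as.numeric(fit$theta_hat)[match(co_names, names(fit$theta_hat))],
                               co_names)
  wb <- widen_bounds(fit, co_names, cfg)
  # re-evaluate the center so the profile and fit objective agree exactly
  center <- reopt_point(model, data, center_co,
                        c(fit$fixed, stats::setNames(center_val, param)),
                        wb$lower, wb$upper, prior, cmp)
  if (!center$ok)
    stop("objective could not be evaluated at the fitted optimum", call. = FALSE)
  if (length(center$co)) center_co <- center$co

  up <- scan_direction(model, data, param, +1, center_val, center$pl, center_co,
                       fit$fixed, wb$lower, wb$upper, prior, cfg, chi2,
                       fit$objective, cmp)
  dn <- scan_direction(model, data, param, -1, center_val, center$pl, center_co,
                       fit$fixed, wb$lower, wb$upper, prior, cfg, chi2,
                       fit$objective, cmp)

  grid <- c(rev(dn$vals), center_val, up$vals)
  pl <- c(rev(dn$pls), center$pl, up$pls)
  path <- matrix(NA_real_, length(grid), length(fit$free),
                 dimnames = list(NULL, fit$free))
  rows <- c(rev(dn$cos), list(center_co), up$cos)
  for (i in seq_along(rows)) {
    if (length(co_names)) path[i, co_names] <- rows[[i]][co_names]
    path[i, param] <- grid[[i]]
  }
  structure(list(
    param = param, grid = grid, pl = pl, path = path,
    objective = fit$objective, alpha = alpha,
    threshold = fit$objective + chi2,
    end_status = c(lower = dn$status, upper = up$status),
    refined = c(lower = dn$refined, upper = up$refined),
    theta_hat = fit$theta_hat, step_config = cfg),
    class = "pl_profile")
}

#' @keywords internal
widen_bounds <- function(fit, co_names, cfg) {
  if (!length(co_names) || is.null(fit$bounds))
    return(list(lower = numeric(), upper = numeric()))
  list(lower = fit$bounds$lower[co_names] - cfg$scan_range,
       upper = fit$bounds$upper[co_names] + cfg$scan_range)
}

#' Profile every free parameter of a fit
#'
#' @inheritParams profile_likelihood
#' @param params parameters to profile (default: all free)
#' @return named list of `pl_profile` objects
#' @export
profile_all <- function(model, data, fit, params = fit$free, alpha = 0.95,
                        step_config = profile_step_config(), prior = NULL) {
  out <- lapply(params, function(p)
    profile_likelihood(model, data, fit, p, alpha, step_config, prior))
  names(out) <- params
  out
}

#' Profile-likelihood confidence interval
#'
#' Finite endpoints are the chi-square threshold crossings (refined during the
#' scan when available, linear interpolation otherwise); a direction whose
#' scan flattened out or reached the scan limit below the threshold yields an
#' infinite endpoint (open confidence interval).
#'
#' @param profile a `pl_profile`
#' @param alpha confidence level; defaults to the profile's own
#' @return object of class `pl_ci`: list(lower, upper, alpha) on the log10
#'   scale
#' @export
confidence_interval <- function(profile, alpha = profile$alpha) {
  chi2 <- chi2_threshold(alpha, 1L)
  threshold <- profile$objective + chi2
  if (min(profile$pl) > threshold + 1e-9)
    stop("profile minimum lies above the threshold; the fit is inconsistent",
         call. = FALSE)
  center_val <- as.numeric(profile$theta_hat[[profile$param]])
  ci_dir <- function(side) {
    status <- profile$end_status[[side]]
    if (status %in% c("flattened", "hit_scan_limit")) {
      edge_pl <- if (side == "lower") profile$pl[[1L]]
                 else profile$pl[[length(profile$pl)]]
      if (edge_pl <= threshold) return(if (side == "lower") -Inf else Inf)
    }
    if (isTRUE(abs(alpha - profile$alpha) < 1e-12) &&
        is.finite(profile$refined[[side]]))
      return(profile$refined[[side]])
    # linear interpolation of the first crossing away from the centre
    g <- profile$grid
    p <- profile$pl
    if (side == "lower") { g <- rev(g); p <- rev(p) }
    start <- which.min(abs(g - center_val))
    for (i in seq(start, length(g) - 1L)) {
      if (p[[i]] <= threshold && p[[i + 1L]] > threshold) {
        w <- (threshold - p[[i]]) / (p[[i + 1L]] - p[[i]])
        return(g[[i]] + w * (g[[i + 1L]] - g[[i]]))
      }
    }
    if (side == "lower") -Inf else Inf
  }
  structure(list(lower = ci_dir("lower"), upper = ci_dir("upper"),
                 alpha = alpha, param = profile$param),
            class = "pl_ci")
}

#' Locate the local minima of a profile
#'
#' Finds interior grid points whose PL value is below both neighbours, merges
#' runs of near-equal values, and keeps minima with at least `min_prominence`
#' depth relative to the lower of the two enclosing maxima. Used to read off
#' interchangeable-optima structure (e.g. the two optima of a conversion
#' chain with an unobserved intermediate).
#'
#' @param profile a `pl_profile`
#' @param min_prominence required depth below the enclosing barrier
#' @param refine interpolate each minimum location as the vertex of the
#'   parabola through its three surrounding grid points (the adaptive grid is
#'   coarse inside shallow basins, where steps grow towards the cap)
#' @return data.frame with `location` (log10 scan value) and `value` (PL),
#'   ordered by location
#' @export
profile_local_minima <- function(profile, min_prominence = 0.05,
                                 refine = TRUE) {
  g <- profile$grid
  p <- profile$pl
  n <- length(g)
  if (n < 3L) return(data.frame(location = numeric(), value = numeric()))
  cand <- which(vapply(2:(n - 1L), function(i)
    p[i] <= p[i - 1L] && p[i] <= p[i + 1L], logical(1L))) + 1L
  if (!length(cand)) return(data.frame(location = numeric(), value = numeric()))
  keep <- logical(length(cand))
  for (j in seq_along(cand)) {
    i <- cand[[j]]
    left_max <- max(p[1:i])
    right_max <- max(p[i:n])
    # barriers relative to neighbouring candidate minima, not the global ends
    lo <- if (j > 1L) max(p[cand[[j - 1L]]:i]) else left_max
    hi <- if (j < length(cand)) max(p[i:cand[[j + 1L]]]) else right_max
    keep[[j]] <- min(lo, hi) - p[i] >= min_prominence
  }
  cand <- cand[keep]
  # merge candidates closer than one step with near-equal PL
  if (length(cand) > 1L) {
    merged <- cand[[1L]]
    for (i in cand[-1L]) {
      if (abs(g[i] - g[utils::tail(merged, 1L)]) < 0.05 &&
          abs(p[i] - p[utils::tail(merged, 1L)]) < 1e-6) next
      merged <- c(merged, i)
    }
    cand <- merged
  }
  loc <- g[cand]
  val <- p[cand]
  if (refine) {
    for (j in seq_along(cand)) {
      i <- cand[[j]]
      if (i <= 1L || i >= n) next
      x <- g[(i - 1L):(i + 1L)]
      y <- p[(i - 1L):(i + 1L)]
      denom <- (x[1] - x[2]) * (x[1] - x[3]) * (x[2] - x[3])
      if (abs(denom) < 1e-12) next
      a <- (x[3] * (y[2] - y[1]) + x[2] * (y[1] - y[3]) +
              x[1] * (y[3] - y[2])) / denom
      b <- (x[3]^2 * (y[1] - y[2]) + x[2]^2 * (y[3] - y[1]) +
              x[1]^2 * (y[2] - y[3])) / denom
      if (a <= 0) next
      v <- -b / (2 * a)
      if (v > x[1] && v < x[3]) {
        loc[[j]] <- v
        val[[j]] <- a * v^2 + b * v +
          (y[1] - a * x[1]^2 - b * x[1])
      }
    }
  }
  data.frame(location = loc, value = val)
}

#' @export
print.pl_profile <- function(x, ...) {
  cat(sprintf("<pl_profile '%s': %d points, status lower=%s upper=%s>\n",
              x$param, length(x$grid), x$end_status[["lower"]],
              x$end_status[["upper"]]))
  invisible(x)
}

#' @export
print.pl_ci <- function(x, ...) {
  cat(sprintf("%d%% CI for log10(%s): [%.4g, %.4g]\n", round(100 * x$alpha),
              x$param, x$lower, x$upper))
  invisible(x)
}

#' Plot a profile likelihood
#'
#' @param x a `pl_profile`
#' @param ... passed to [plot()]
#' @export
plot.pl_profile <- function(x, ...) {
  graphics::plot(x$grid, x$pl, type = "l", xlab = sprintf("log10(%s)", x$param),
                 ylab = "-2 log L", ...)
  graphics::abline(h = x$threshold, lty = 2)
  graphics::points(as.numeric(x$theta_hat[[x$param]]), min(x$pl), pch = 19)
  invisible(x)
}
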