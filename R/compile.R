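# Compile a model_spec into evaluable functions: the ODE right-hand side
# assembled stoichiometrically from the reaction rate laws, the forward
# sensitivity system with respect to log10-scale parameters, and the
# observation map with its derivatives. Algebraic assignments, time-dependent
# inputs and fixed parameters are inlined symbolically before differentiation,
# so the generated system is closed over dynamic states, free parameters and t.

.LN10 <- "2.302585092994046"  # log(10), inlined into generated code

#' Compute the stoichiometry matrix of a model
#'
#' Rows are dynamic states, columns reactions; entries are net molecule
#' changes (products minus substrates, with multiplicity).
#' @param model a `model_spec`
#' @return integer matrix
#' @export
stoichiometry <- function(model) {
  dyn <- dynamic_states(model)
  nr <- length(model$reactions)
  S <- matrix(0L, nrow = length(dyn), ncol = nr,
              dimnames = list(dyn, vapply(model$reactions, `[[`, "", "id")))
  for (j in seq_len(nr)) {
    rx <- model$reactions[[j]]
    for (s in rx$substrates) if (s %in% dyn) S[s, j] <- S[s, j] - 1L
    for (s in rx$products) if (s %in% dyn) S[s, j] <- S[s, j] + 1L
  }
  S
}

#' @keywords internal
model_key <- function(model) {
  core <- list(model$states, model$initials,
               lapply(model$reactions, `[[`, "text"),
               model$inputs, model$observables, model$errors,
               model$assignments, model$fixed)
  paste(deparse(core), collapse = "")
}

#' Substitutions inlining fixed parameters, inputs and assignments
#' @keywords internal
model_substitutions <- function(model) {
  subs <- list()
  for (nm in names(model$fixed)) subs[[nm]] <- model$fixed[[nm]]
  for (nm in names(model$inputs))
    subs[[nm]] <- call("(", substitute_expr(
      parse_expr(model$inputs[[nm]], sprintf("input %s", nm)), subs))
  for (nm in names(model$assignments)) {
    ex <- parse_expr(model$assignments[[nm]], sprintf("assignment of %s", nm))
    subs[[nm]] <- call("(", inline_all(ex, subs))
  }
  subs
}

.compile_cache <- new.env(parent = emptyenv())

#' Compile (or fetch the cached compilation of) a model
#'
#' Generates evaluable R functions for the assembled ODE system, the forward
#' sensitivity system and the observation map, and (when a compiler is
#' available) a compiled C backend for the integrator. Compilations are cached
#' for the session, keyed by the model structure.
#'
#' @param model a `model_spec`
#' @return an environment with the generated functions; users normally never
#'   call this directly.
#' @export
compile_model <- function(model) {
  cached <- attr(model, "compiled")
  if (!is.null(cached)) return(cached)
  key <- model_key(model)
  cached <- .compile_cache[[key]]
  if (!is.null(cached)) return(cached)

  validate_model_spec(model)
  dyn <- dynamic_states(model)
  theta <- free_parameters(model)
  nx <- length(dyn)
  np <- length(theta)
  subs <- model_substitutions(model)
  S <- stoichiometry(model)

  rate_exprs <- lapply(model$reactions, function(rx)
    inline_all(parse_expr(rx$rate, sprintf("rate of %s", rx$id)), subs))

  # f_j = sum_r S[j, r] * rate_r
  f_strs <- vapply(seq_len(nx), function(j) {
    terms <- character()
    for (r in seq_along(rate_exprs)) {
      if (S[j, r] == 0L) next
      coef <- if (S[j, r] == 1L) "" else if (S[j, r] == -1L) "-"
              else sprintf("%d * ", S[j, r])
      op <- if (S[j, r] < 0L && S[j, r] != -1L) "" else ""
      terms <- c(terms, sprintf("%s(%s)", coef, deparse1_(rate_exprs[[r]])))
    }
    if (!length(terms)) "0" else paste(terms, collapse = " + ")
  }, character(1L))
  f_exprs <- lapply(f_strs, function(s) parse_expr(s, "assembled RHS"))

  # state Jacobian (column-major: d f_j / d x_i, j fast) and parameter
  # Jacobian w.r.t. log10 theta (chain rule theta * ln 10), as language objects
  jx_exprs <- list()
  for (i in seq_len(nx)) for (j in seq_len(nx))
    jx_exprs <- c(jx_exprs, list(diff_expr(f_exprs[[j]], dyn[[i]])))
  ln10 <- log(10)
  jp_exprs <- list()
  for (k in seq_len(np)) for (j in seq_len(nx)) {
    d <- diff_expr(f_exprs[[j]], theta[[k]])
    chained <- if (identical(d, 0) || identical(d, 0L)) 0
               else call("*", call("*", call("(", d), as.name(theta[[k]])), ln10)
    jp_exprs <- c(jp_exprs, list(chained))
  }
  jx_strs <- vapply(jx_exprs, function(e) sprintf("(%s)", deparse1_(e)),
                    character(1L))
  jp_strs <- vapply(jp_exprs, function(e) sprintf("(%s)", deparse1_(e)),
                    character(1L))

  header <- c(
    vapply(seq_len(nx), function(j) sprintf("  %s <- y[[%d]]", dyn[[j]], j),
           character(1L)),
    vapply(seq_len(np), function(k) sprintf("  %s <- parms[[%d]]", theta[[k]], k),
           character(1L)))
  f_line <- sprintf("  .f <- c(%s)", paste(f_strs, collapse = ", "))

  f_fun <- eval(parse(text = paste(c(
    "function(t, y, parms) {", header, f_line, "  list(.f)", "}"),
    collapse = "\n")), envir = baseenv())

  fs_fun <- eval(parse(text = paste(c(
    "function(t, y, parms) {", header, f_line,
    sprintf("  .S <- matrix(y[-seq_len(%d)], %d, %d)", nx, nx, np),
    sprintf("  .Jx <- matrix(c(%s), %d, %d)", paste(jx_strs, collapse = ", "), nx, nx),
    sprintf("  .Jp <- matrix(c(%s), %d, %d)", paste(jp_strs, collapse = ", "), nx, np),
    "  list(c(.f, .Jx %*% .S + .Jp))", "}"), collapse = "\n")),
    envir = baseenv())

  # initial conditions and initial sensitivities
  x0_fun <- function(theta_nat) {
    vapply(dyn, function(s) {
      v <- model$initials[[s]]
      if (is.character(v)) theta_nat[[v]] else as.numeric(v)
    }, numeric(1L))
  }
  s0_fun <- function(theta_nat) {
    s0 <- matrix(0, nx, np, dimnames = list(dyn, theta))
    for (s in dyn) {
      v <- model$initials[[s]]
      if (is.character(v)) s0[s, v] <- theta_nat[[v]] * log(10)
    }
    s0
  }

  # observation map: g, dg/dx, dg/dlog10theta (all vectorised over time)
  obs_names <- names(model$observables)
  g_exprs <- lapply(obs_names, function(o)
    inline_all(parse_expr(model$observables[[o]], sprintf("observable %s", o)), subs))
  names(g_exprs) <- obs_names
  dgdx <- lapply(g_exprs, function(g) lapply(dyn, function(s) diff_expr(g, s)))
  dgdp <- lapply(g_exprs, function(g) lapply(theta, function(p) diff_expr(g, p)))

  eval_env <- function(times, xmat, theta_nat) {
    e <- new.env(parent = baseenv())
    assign(.TIME_SYMBOL, times, envir = e)
    for (j in seq_len(nx)) assign(dyn[[j]], xmat[, j], envir = e)
    for (k in seq_len(np)) assign(theta[[k]], theta_nat[[k]], envir = e)
    e
  }
  obs_fun <- function(times, xmat, theta_nat) {
    e <- eval_env(times, xmat, theta_nat)
    out <- matrix(NA_real_, length(times), length(obs_names),
                  dimnames = list(NULL, obs_names))
    for (o in obs_names) out[, o] <- rep_len(eval(g_exprs[[o]], e), length(times))
    out
  }
  # sens: array time x state x param -> returns array time x obs x param
  obs_jac_fun <- function(times, xmat, sens, theta_nat) {
    e <- eval_env(times, xmat, theta_nat)
    nt <- length(times)
    out <- array(0, c(nt, length(obs_names), np),
                 dimnames = list(NULL, obs_names, theta))
    for (oi in seq_along(obs_names)) {
      for (j in seq_len(nx)) {
        d <- eval(dgdx[[oi]][[j]], e)
        if (!identical(d, 0)) out[, oi, ] <- out[, oi, ] +
            rep_len(d, nt) * sens[, j, , drop = TRUE]
      }
      for (k in seq_len(np)) {
        d <- eval(dgdp[[oi]][[k]], e)
        if (!identical(d, 0)) out[, oi, k] <- out[, oi, k] +
            rep_len(d, nt) * theta_nat[[k]] * log(10)
      }
    }
    out
  }
  # assigned-state columns from dynamic trajectory
  assigned_names <- names(model$assignments)
  assigned_exprs <- lapply(assigned_names, function(s)
    inline_all(parse_expr(model$assignments[[s]], "assignment"), subs))
  names(assigned_exprs) <- assigned_names
  assigned_fun <- function(times, xmat, theta_nat) {
    if (!length(assigned_names)) return(NULL)
    e <- eval_env(times, xmat, theta_nat)
    out <- matrix(NA_real_, length(times), length(assigned_names),
                  dimnames = list(NULL, assigned_names))
    for (s in assigned_names) out[, s] <- rep_len(eval(assigned_exprs[[s]], e),
                                                  length(times))
    out
  }

  env <- new.env(parent = emptyenv())
  env$key <- key
  env$dyn <- dyn
  env$theta <- theta
  env$nx <- nx
  env$np <- np
  env$f_fun <- f_fun
  env$fs_fun <- fs_fun
  env$x0_fun <- x0_fun
  env$s0_fun <- s0_fun
  env$obs_fun <- obs_fun
  env$obs_jac_fun <- obs_jac_fun
  env$assigned_fun <- assigned_fun
  env$cback <- tryCatch(
    compile_c_backend(f_exprs, jx_exprs, jp_exprs, dyn, theta),
    error = function(e) NULL)
  .compile_cache[[key]] <- env
  env
}

#' Attach a compiled representation to a model (cached)
#' @keywords internal
with_compiled <- function(model) {
  attr(model, "compiled") <- compile_model(model)
  model
}

#' Assemble the ODE right-hand side of a model
#'
#' Returns the stoichiometric sum of the reaction rate laws as an R function
#' `f(x, theta, t)` with `x` a named state vector and `theta` a named
#' natural-scale parameter vector. Algebraic assignments and inputs are
#' substituted before assembly, so `f` covers dynamic states only.
#' @param model a `model_spec`
#' @return function of `(x, theta, t)` returning the state derivative vector
#' @export
assemble_odes <- function(model) {
  cmp <- compile_model(model)
  function(x, theta, t = 0) {
    y <- as.numeric(x[cmp$dyn])
    p <- as.numeric(theta[cmp$theta])
    out <- cmp$f_fun(t, y, p)[[1L]]
    names(out) <- cmp$dyn
    out
  }
}
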