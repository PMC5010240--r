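# Optional C backend: the assembled ODE right-hand side and its forward
# sensitivity system are translated to C, compiled with R CMD SHLIB and
# integrated through deSolve's compiled-code interface. Falls back to the
# generated R functions when no compiler is available. Compilations are cached
# per session and keyed by the model structure.

#' Translate an R arithmetic expression to C
#' @param e language object
#' @param symmap named character vector mapping symbol -> C lvalue
#' @keywords internal
r_expr_to_c <- function(e, symmap) {
  if (is.numeric(e)) {
    if (length(e) != 1L) stop("vector literal in expression")
    return(sprintf("%.17g", e))
  }
  if (is.symbol(e)) {
    nm <- as.character(e)
    if (nm == "pi") return("3.14159265358979312")
    out <- symmap[[nm]]
    if (is.null(out)) stop("unknown symbol in C translation: ", nm)
    return(out)
  }
  if (is.call(e)) {
    op <- as.character(e[[1L]])
    args <- lapply(as.list(e)[-1L], r_expr_to_c, symmap = symmap)
    return(switch(op,
      "+" = if (length(args) == 1L) sprintf("(+%s)", args[[1L]])
            else sprintf("(%s + %s)", args[[1L]], args[[2L]]),
      "-" = if (length(args) == 1L) sprintf("(-%s)", args[[1L]])
            else sprintf("(%s - %s)", args[[1L]], args[[2L]]),
      "*" = sprintf("(%s * %s)", args[[1L]], args[[2L]]),
      "/" = sprintf("(%s / %s)", args[[1L]], args[[2L]]),
      "^" = sprintf("pow(%s, %s)", args[[1L]], args[[2L]]),
      "(" = sprintf("(%s)", args[[1L]]),
      "exp" = , "log" = , "sqrt" = , "sin" = , "cos" = , "tan" = ,
      "sinh" = , "cosh" = , "tanh" = , "log10" = , "log2" =
        sprintf("%s(%s)", op, args[[1L]]),
      "abs" = sprintf("fabs(%s)", args[[1L]]),
      stop("unsupported function in C translation: ", op)))
  }
  stop("unsupported expression element in C translation")
}

#' @keywords internal
.codegen_state <- new.env(parent = emptyenv())
.codegen_state$counter <- 0L
.codegen_state$compiler_ok <- NA  # memoised availability of R CMD SHLIB

#' Generate, compile and load the C backend for a model
#'
#' @param f_exprs list of RHS expressions (dynamic states)
#' @param jx_exprs,jp_exprs Jacobian expressions, column-major lists
#' @param dyn,theta state and parameter names
#' @return list(dllname, f, fs, init) or NULL when compilation is unavailable
#' @keywords internal
compile_c_backend <- function(f_exprs, jx_exprs, jp_exprs, dyn, theta) {
  if (isFALSE(.codegen_state$compiler_ok)) return(NULL)
  nx <- length(dyn)
  np <- length(theta)
  symmap <- c(
    stats::setNames(sprintf("y[%d]", seq_len(nx) - 1L), dyn),
    stats::setNames(sprintf("p[%d]", seq_len(np) - 1L), theta),
    stats::setNames("T", .TIME_SYMBOL))
  tr <- function(e) r_expr_to_c(e, as.list(symmap))
  c_f <- vapply(f_exprs, tr, character(1L))
  c_jx <- vapply(jx_exprs, tr, character(1L))
  c_jp <- vapply(jp_exprs, tr, character(1L))

  .codegen_state$counter <- .codegen_state$counter + 1L
  tag <- sprintf("plrmod_%d_%d", Sys.getpid(), .codegen_state$counter)

  lines <- c(
    "#include <R.h>",
    "#include <math.h>",
    sprintf("static double p[%d];", max(np, 1L)),
    sprintf("void %s_init(void (* odeparms)(int *, double *)) {", tag),
    sprintf("  int N = %d; odeparms(&N, p);", np),
    "}",
    sprintf("void %s_f(int *neq, double *t, double *y, double *ydot, double *yout, int *ip) {", tag),
    "  double T = *t; (void) T; (void) yout; (void) ip; (void) neq;",
    sprintf("  ydot[%d] = %s;", seq_len(nx) - 1L, c_f),
    "}",
    sprintf("void %s_fs(int *neq, double *t, double *y, double *ydot, double *yout, int *ip) {", tag),
    "  double T = *t; (void) T; (void) yout; (void) ip; (void) neq;",
    sprintf("  double Jx[%d]; double Jp[%d];", nx * nx, max(nx * np, 1L)),
    sprintf("  ydot[%d] = %s;", seq_len(nx) - 1L, c_f),
    sprintf("  Jx[%d] = %s;", seq_len(nx * nx) - 1L, c_jx),
    if (np > 0L) sprintf("  Jp[%d] = %s;", seq_len(nx * np) - 1L, c_jp),
    "  int i, j, k;",
    sprintf("  for (k = 0; k < %d; k++) {", np),
    sprintf("    for (j = 0; j < %d; j++) {", nx),
    sprintf("      double acc = Jp[k * %d + j];", nx),
    sprintf("      for (i = 0; i < %d; i++) acc += Jx[i * %d + j] * y[%d + k * %d + i];",
            nx, nx, nx, nx),
    sprintf("      ydot[%d + k * %d + j] = acc;", nx, nx),
    "    }",
    "  }",
    "}")

  src <- file.path(tempdir(), paste0(tag, ".c"))
  writeLines(lines, src)
  rbin <- file.path(R.home("bin"), "R")
  so <- file.path(tempdir(), paste0(tag, .Platform$dynlib.ext))
  owd <- setwd(tempdir())
  on.exit(setwd(owd), add = TRUE)
  tryCatch(
    system2(rbin, c("CMD", "SHLIB", shQuote(basename(src))),
            stdout = TRUE, stderr = TRUE),
    error = function(e) NULL)
  if (!file.exists(so)) {
    .codegen_state$compiler_ok <- FALSE
    return(NULL)
  }
  ok <- tryCatch({ dyn.load(so); TRUE }, error = function(e) FALSE)
  if (!ok) {
    .codegen_state$compiler_ok <- FALSE
    return(NULL)
  }
  .codegen_state$compiler_ok <- TRUE
  list(dllname = tag, f = paste0(tag, "_f"), fs = paste0(tag, "_fs"),
       init = paste0(tag, "_init"))
}
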