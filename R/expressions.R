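# Small symbolic toolkit used to turn rate-law / observable strings into
# evaluable and differentiable R expressions. Only closed-form arithmetic
# that stats::D can differentiate is supported.

.TIME_SYMBOL <- "t"

#' Parse an expression string into an R language object
#' @param text single character string
#' @param where label used in error messages
#' @return a call or symbol or numeric literal
#' @keywords internal
parse_expr <- function(text, where = "expression") {
  if (is.numeric(text)) return(text)
  stopifnot(is.character(text), length(text) == 1L)
  parsed <- tryCatch(parse(text = text, keep.source = FALSE),
                     error = function(e) {
                       stop(sprintf("cannot parse %s '%s': %s", where, text,
                                    conditionMessage(e)), call. = FALSE)
                     })
  if (length(parsed) != 1L)
    stop(sprintf("%s '%s' must be a single expression", where, text), call. = FALSE)
  parsed[[1L]]
}

#' Symbols occurring in an expression string
#' @keywords internal
expr_symbols <- function(text, where = "expression") {
  all.vars(parse_expr(text, where))
}

#' Substitute symbols in an expression
#'
#' @param expr language object
#' @param subs named list mapping symbol name -> language object or numeric
#' @keywords internal
substitute_expr <- function(expr, subs) {
  if (length(subs) == 0L) return(expr)
  do.call(substitute, list(expr, subs))
}

#' Deparse to a single-line string
#' @keywords internal
deparse1_ <- function(expr) paste(deparse(expr, width.cutoff = 500L), collapse = " ")

#' Differentiate an expression with respect to a symbol
#' @keywords internal
diff_expr <- function(expr, name) {
  tryCatch(stats::D(expr, name),
           error = function(e) {
             stop(sprintf("cannot differentiate '%s' with respect to '%s': %s",
                          deparse1_(expr), name, conditionMessage(e)),
                  call. = FALSE)
           })
}

#' Repeatedly substitute assignment expressions until fixed point
#'
#' Used to inline algebraic assignments (and time-dependent inputs) into rate
#' and observable expressions before differentiation. Cycles raise an error.
#' @keywords internal
inline_all <- function(expr, subs, max_depth = 25L) {
  for (i in seq_len(max_depth)) {
    hit <- any(all.vars(expr) %in% names(subs))
    if (!hit) return(expr)
    expr <- substitute_expr(expr, subs)
  }
  if (any(all.vars(expr) %in% names(subs)))
    stop("cyclic algebraic assignment detected while inlining expressions",
         call. = FALSE)
  expr
}
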