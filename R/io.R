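# File formats: the YAML model-definition dialect (sections states/initials/
# reactions/inputs/observables/errors/assignments/fixed, reaction syntax
# "A -> B ; rate"), the measurement CSV (observable,time,value,sigma) and
# stable-key JSON reports.

#' Serialise a model to the YAML model-definition format
#'
#' @param model a `model_spec`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_model_yaml <- function(model, path) {
  doc <- list(
    name = model$name,
    states = as.list(model$states),
    initials = model$initials,
    reactions = lapply(model$reactions, format_reaction),
    inputs = model$inputs,
    observables = model$observables,
    errors = model$errors,
    assignments = model$assignments,
    fixed = as.list(model$fixed))
  yaml::write_yaml(doc, path, precision = 15L)
  invisible(path)
}

#' Parse a YAML model-definition file
#'
#' @param path file to read
#' @return a validated `model_spec`
#' @export
read_model_yaml <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path, call. = FALSE)
  doc <- tryCatch(yaml::read_yaml(path), error = function(e)
    stop(sprintf("cannot parse model file '%s': %s", path,
                 conditionMessage(e)), call. = FALSE))
  need <- c("states", "observables")
  missing <- setdiff(need, names(doc))
  if (length(missing))
    stop(sprintf("model file '%s' is missing section(s): %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  model_spec(
    name = doc$name %||% sub("\\.[^.]*$", "", basename(path)),
    states = unlist(doc$states),
    initials = doc$initials,
    reactions = unlist(doc$reactions),
    inputs = unlist(doc$inputs) %||% character(),
    observables = unlist(doc$observables),
    errors = doc$errors,
    assignments = unlist(doc$assignments) %||% character(),
    fixed = unlist(doc$fixed) %||% numeric())
}

#' Read a measurement CSV (columns observable,time,value,sigma)
#'
#' @param path CSV file, header required, '.' decimal separator
#' @return a `pl_dataset`
#' @export
read_dataset <- function(path) {
  if (!file.exists(path)) stop("data file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("observable", "time", "value", "sigma")
  missing <- setdiff(need, names(raw))
  if (length(missing))
    stop(sprintf("data file '%s' is missing column(s): %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  for (col in c("time", "value", "sigma")) {
    v <- raw[[col]]
    if (!is.numeric(v)) {
      coerced <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(coerced) & !is.na(v))
      if (length(bad))
        stop(sprintf("non-numeric '%s' in data row %d of '%s'", col, bad[[1L]],
                     path), call. = FALSE)
      raw[[col]] <- coerced
    }
  }
  dataset(raw)
}

#' Write a dataset to CSV
#' @export
write_dataset <- function(data, path) {
  utils::write.csv(as.data.frame(data)[c("observable", "time", "value",
                                         "sigma")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write an R object as a JSON report / read it back
#'
#' Reports use stable keys, unboxed scalars and full numeric precision.
#' @param obj a list-like report object
#' @param path output file
#' @export
write_report <- function(obj, path) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null", null = "null")
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Assemble a JSON-ready fit report
#'
#' @param fit a `fit_result`
#' @return list with the estimate on both scales, the objective and the
#'   multistart table
#' @export
fit_report <- function(fit) {
  list(
    objective = fit$objective,
    theta_log10 = as.list(stats::setNames(as.numeric(fit$theta_hat),
                                          names(fit$theta_hat))),
    theta_natural = as.list(stats::setNames(10^as.numeric(fit$theta_hat),
                                            names(fit$theta_hat))),
    free = as.list(fit$free),
    fixed = as.list(fit$fixed),
    n_starts = nrow(fit$multistart),
    seed = fit$seed,
    multistart = fit$multistart)
}

#' Export a profile scan as CSV
#'
#' Columns: `param`, `scan_value_log10`, `PL`, then one column per
#' co-parameter path.
#' @param profile a `pl_profile`
#' @param path output file
#' @export
write_profile_csv <- function(profile, path) {
  co <- setdiff(colnames(profile$path), profile$param)
  df <- data.frame(param = profile$param,
                   scan_value_log10 = profile$grid,
                   PL = profile$pl)
  for (p in co) df[[p]] <- profile$path[, p]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Assemble a JSON-ready profile summary
#' @param profile a `pl_profile`
#' @export
profile_report <- function(profile) {
  ci <- confidence_interval(profile)
  json_num <- function(x) if (is.finite(x)) x else as.character(x)  # +-Inf
  list(param = profile$param,
       alpha = profile$alpha,
       objective = profile$objective,
       threshold = profile$threshold,
       n_points = length(profile$grid),
       end_status = as.list(profile$end_status),
       ci_log10 = list(lower = json_num(ci$lower), upper = json_num(ci$upper)))
}
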