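# JSON parameter files: save an operation's configuration, reload it,
# reproduce the run. Schema (this package's own dialect, not byte-compatible
# with other tools): {"command": str, "version": str, "parameters": {...}}.
# Files are UTF-8, 2-space indented, with recursively sorted keys so equal
# configurations serialize to identical bytes.

#' Construct an operation configuration
#'
#' @param command a registered command name (see [list_commands()]).
#' @param parameters named list of parameter values (scalars, vectors or
#'   nested named lists).
#' @param version toolkit version string recorded in the file.
#' @param validate check the command is registered and each parameter name
#'   is known to it.
#' @return an object of class `operation_config`.
#' @export
operation_config <- function(command, parameters = list(),
                             version = as.character(utils::packageVersion("fastaforge")),
                             validate = TRUE) {
  if (!is.list(parameters) ||
      (length(parameters) > 0 &&
       (is.null(names(parameters)) || any(!nzchar(names(parameters))))))
    usage_error("parameters must be a named list")
  if (validate) validate_config_names(command, names(parameters))
  structure(list(command = command, version = version,
                 parameters = parameters),
            class = "operation_config")
}

validate_config_names <- function(command, param_names) {
  desc <- get_command(command)  # errors if unregistered
  known <- desc$params$name
  unknown <- setdiff(param_names, known)
  if (length(unknown))
    usage_error(sprintf("unknown parameter '%s' for command '%s'",
                        unknown[1], command))
  invisible(TRUE)
}

sort_keys <- function(x) {
  if (is.list(x) && !is.null(names(x)) && length(x) > 0) {
    x <- x[order(names(x), method = "radix")]
    lapply(x, sort_keys)
  } else x
}

#' Save an operation configuration to a JSON parameter file
#'
#' Keys are sorted recursively, so two saves of the same configuration are
#' byte-identical.
#'
#' @param config an [operation_config()].
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
save_parameters <- function(config, path) {
  stopifnot(inherits(config, "operation_config"))
  obj <- list(command = config$command,
              parameters = sort_keys(config$parameters),
              version = config$version)
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, pretty = 2, digits = NA,
                           null = "null")
  dir <- dirname(path)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  writeLines(json, path, useBytes = TRUE)
  invisible(path)
}

#' Load an operation configuration from a JSON parameter file
#'
#' Unknown parameter names are rejected rather than silently ignored; a
#' file written for another command is rejected when `expected_command` is
#' given.
#'
#' @param path a file written by [save_parameters()] (or by hand, matching
#'   the schema).
#' @param expected_command command name of the caller, for mismatch checks.
#' @return an [operation_config()].
#' @export
load_parameters <- function(path, expected_command = NULL) {
  if (!file.exists(path)) input_error(sprintf("parameters file '%s' not found", path))
  obj <- tryCatch(jsonlite::fromJSON(path, simplifyDataFrame = FALSE,
                                     simplifyMatrix = FALSE),
                  error = function(e)
                    format_error(sprintf("'%s' is not valid JSON: %s", path,
                                         conditionMessage(e))))
  if (!is.list(obj) || is.null(obj$command) || !is.character(obj$command))
    format_error(sprintf("'%s': missing or invalid field 'command'", path))
  if (is.null(obj$parameters)) obj$parameters <- list()
  if (!is.list(obj$parameters))
    format_error(sprintf("'%s': field 'parameters' must be an object", path))
  if (!is.null(expected_command) && !identical(obj$command, expected_command))
    usage_error(sprintf("parameters file '%s' is for command '%s', not '%s'",
                        path, obj$command, expected_command))
  operation_config(obj$command, obj$parameters,
                   version = obj$version %||% NA_character_)
}

#' Overlay command-line arguments on a loaded configuration
#'
#' Precedence: explicit command-line values > file values > command
#' defaults (applied by the command itself).
#'
#' @param file_config an [operation_config()] or `NULL`.
#' @param cli_args named list of explicitly supplied argument values.
#' @return named list of effective parameter values.
#' @export
merge_cli_over_file <- function(file_config, cli_args = list()) {
  eff <- if (is.null(file_config)) list() else file_config$parameters
  for (nm in names(cli_args)) eff[[nm]] <- cli_args[[nm]]
  eff
}
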