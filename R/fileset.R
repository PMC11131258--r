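# File sets: input resolution (directory / explicit files / list file),
# output grouping and the in-memory vs on-disk processing contract.

DEFAULT_FASTA_SUFFIXES <- c(".fasta", ".fa", ".faa", ".fna", ".ffn", ".frn",
                            ".fasta.gz", ".fa.gz", ".faa.gz", ".fna.gz")

new_fileset <- function(paths, origin) {
  paths <- as.character(paths)
  if (anyDuplicated(paths))
    usage_error("paths within a file set must be unique")
  structure(list(paths = paths, origin = origin), class = "file_set")
}

#' @export
print.file_set <- function(x, ...) {
  cat(sprintf("<file_set> %d file(s), origin: %s\n", length(x$paths), x$origin))
  invisible(x)
}

#' Resolve input files from exactly one source
#'
#' Mirrors the common input options of every command: a directory
#' (`--input-directory`), explicit files (repeated `--input-file`) or a
#' plain-text list file (`--input-list`, one path per line, `#` comments
#' and blank lines ignored). Exactly one source must be given.
#'
#' @param input_directory directory scanned (non-recursively) for files with
#'   a recognised FASTA suffix, returned in lexicographic (C locale) order.
#' @param input_files character vector of explicit paths; order kept,
#'   repetitions collapsed to the first occurrence.
#' @param input_list path to a list file; entries are resolved relative to
#'   the list file's directory unless absolute.
#' @param suffixes suffix filter used for directory input.
#' @return a `file_set`.
#' @export
resolve_inputs <- function(input_directory = NULL, input_files = NULL,
                           input_list = NULL,
                           suffixes = DEFAULT_FASTA_SUFFIXES) {
  given <- c(directory = !is.null(input_directory),
             files = !is.null(input_files) && length(input_files) > 0,
             list = !is.null(input_list))
  if (sum(given) != 1L)
    usage_error("exactly one of --input-directory, --input-file or --input-list must be given")
  if (given[["directory"]]) {
    if (!dir.exists(input_directory))
      input_error(sprintf("input directory '%s' does not exist", input_directory))
    all <- list.files(input_directory, full.names = TRUE)
    pat <- paste0("(", paste(gsub("\\.", "\\\\.", suffixes), collapse = "|"), ")$")
    hit <- all[grepl(pat, all, ignore.case = TRUE) & file.exists(all) & !dir.exists(all)]
    return(new_fileset(sort(hit, method = "radix"), "directory"))
  }
  if (given[["files"]]) {
    paths <- unique(as.character(input_files))
    missing <- paths[!file.exists(paths)]
    if (length(missing))
      input_error(sprintf("input file '%s' does not exist", missing[1]))
    return(new_fileset(paths, "explicit-files"))
  }
  if (!file.exists(input_list))
    input_error(sprintf("input list '%s' does not exist", input_list))
  lines <- sub("\r$", "", readLines(input_list, warn = FALSE))
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  base <- dirname(input_list)
  paths <- ifelse(grepl("^(/|[A-Za-z]:)", lines), lines, file.path(base, lines))
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    input_error(sprintf("input list references missing path '%s'", missing[1]))
  new_fileset(unique(paths), "list-file")
}

#' Group result files into fixed-size subdirectories
#'
#' With `group_size = 0` (the default) results stay directly in
#' `output_dir` and no subdirectories are created. With `group_size = N`,
#' files are moved, in input order, into subdirectories `group_1`,
#' `group_2`, ... each holding at most `N` files (all but the last exactly
#' `N`).
#'
#' @param result_paths character vector of files (inside `output_dir`).
#' @param output_dir the output directory.
#' @param group_size files per subdirectory; 0 disables grouping.
#' @return character vector of final paths, in input order.
#' @export
group_outputs <- function(result_paths, output_dir, group_size = 0) {
  if (length(group_size) != 1L || is.na(group_size) || group_size < 0 ||
      group_size != as.integer(group_size))
    usage_error("--output-group-size must be a non-negative integer")
  if (group_size == 0 || length(result_paths) == 0L)
    return(invisible(result_paths))
  grp <- ((seq_along(result_paths) - 1L) %/% group_size) + 1L
  dest <- file.path(output_dir, paste0("group_", grp), basename(result_paths))
  for (dir in unique(dirname(dest))) dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ok <- file.rename(result_paths, dest)
  if (!all(ok)) processing_error("failed to move outputs into group subdirectories")
  invisible(dest)
}

# Instrumentation for the bounded-memory contract of on-disk mode: tracks
# the maximum number of records resident at once during process_fileset().
.ff_stats <- new.env(parent = emptyenv())

#' Peak resident record count of the last [process_fileset()] call
#' @return integer, or NA if nothing was processed yet.
#' @export
last_peak_records <- function() .ff_stats$peak %||% NA_integer_

#' Apply an operation to every file of a file set
#'
#' In `in-memory` mode every input file is loaded before any output is
#' written; in `on-disk` mode files are streamed one at a time so no more
#' than one file's worth of records is resident. The two modes produce
#' byte-identical outputs. A failure on one file is recorded and the
#' remaining files are still processed.
#'
#' @param fileset a `file_set`.
#' @param operation function taking a dataset and returning a dataset or an
#'   operation result (a list with a `dataset` element).
#' @param output_dir directory for result files (created if needed); each
#'   output keeps its input's base name.
#' @param mode `"in-memory"` or `"on-disk"`.
#' @param gzip compress outputs with gzip.
#' @param line_width forwarded to [write_fasta()].
#' @return list with `fileset` (outputs, in input order) and `errors`
#'   (named list of condition messages for failed files).
#' @export
process_fileset <- function(fileset, operation, output_dir,
                            mode = c("in-memory", "on-disk"),
                            gzip = FALSE, line_width = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(fileset, "file_set"))
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- fileset$paths
  outs <- character()
  errors <- list()
  .ff_stats$peak <- 0L
  apply_one <- function(d) {
    r <- operation(d)
    if (inherits(r, "fasta_dataset")) r else r$dataset
  }
  out_name <- function(p) {
    base <- sub("\\.gz$", "", basename(p))
    file.path(output_dir, base)
  }
  if (mode == "in-memory") {
    loaded <- list()
    for (p in paths) {
      loaded[[p]] <- tryCatch(read_fasta(p), ff_error = function(e) e)
    }
    resident <- sum(vapply(loaded, function(x)
      if (inherits(x, "fasta_dataset")) n_records(x) else 0L, integer(1)))
    .ff_stats$peak <- resident
    for (p in paths) {
      res <- loaded[[p]]
      if (!inherits(res, "fasta_dataset")) { errors[[p]] <- conditionMessage(res); next }
      res <- tryCatch(apply_one(res), error = function(e) e)
      if (inherits(res, "error")) { errors[[p]] <- conditionMessage(res); next }
      outs <- c(outs, write_fasta(res, out_name(p), gzip = gzip, line_width = line_width))
    }
  } else {
    for (p in paths) {
      res <- tryCatch({
        d <- read_fasta(p)
        .ff_stats$peak <- max(.ff_stats$peak, n_records(d))
        apply_one(d)
      }, error = function(e) e)
      if (inherits(res, "error")) { errors[[p]] <- conditionMessage(res); next }
      outs <- c(outs, write_fasta(res, out_name(p), gzip = gzip, line_width = line_width))
    }
  }
  list(fileset = new_fileset(outs, "explicit-files"), errors = errors)
}
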