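# Command registry: one descriptor per CLI command, carrying the
# command-specific options plus the common option set shared by every
# command (input source, output directory/grouping/gzip, in-disk
# processing, parameter files). The registry is the single source of truth
# for CLI parsing, help text, man pages and parameter-file validation.

opt <- function(name, short = NULL, type = "str", default = NULL, help = "",
                category = "specific") {
  list(name = name, short = short, type = type, default = default,
       help = help, category = category)
}

common_options <- function() {
  list(
    opt("input-directory", "id", "str", NULL,
        "Path to the folder containing the files to process", "input"),
    opt("input-file", "if", "strs", NULL,
        "Path to the file to process; may be given multiple times", "input"),
    opt("input-list", "il", "str", NULL,
        "Plain-text file with the paths of the files to process", "input"),
    opt("output-directory", "od", "str", NULL,
        "Path to the folder to be created where result files will be saved",
        "output"),
    opt("output-group-size", "sz", "int", 0L,
        "Split output files into subdirectories of this size; 0 disables splitting",
        "output"),
    opt("output-gzip", "gz", "flag", FALSE,
        "Compress the output files using gzip", "output"),
    opt("in-disk-processing", "dp", "flag", FALSE,
        "Process files on disk one at a time instead of loading all in memory",
        "configuration"),
    opt("parameters-file", "pf", "str", NULL,
        "File with the command configuration to load the command options",
        "command-configuration-files"),
    opt("save-parameters-file", "spf", "str", NULL,
        "File to save the command configuration options for later reuse",
        "command-configuration-files"))
}

.registry <- new.env(parent = emptyenv())

register_command <- function(name, summary, options, executor) {
  .registry[[name]] <- list(
    name = name, summary = summary, options = options, executor = executor,
    params = data.frame(name = vapply(options, `[[`, character(1), "name"),
                        stringsAsFactors = FALSE))
  invisible(name)
}

#' List registered command names
#' @return sorted character vector.
#' @export
list_commands <- function() sort(ls(.registry))

#' Retrieve a command descriptor
#' @param name command name.
#' @return descriptor list (name, summary, options, params).
#' @export
get_command <- function(name) {
  d <- .registry[[name]]
  if (is.null(d)) usage_error(sprintf("unknown command '%s'", name))
  d
}

# wraps a per-dataset operation into the standard executor signature
dataset_executor <- function(make_op) {
  function(fileset, params, output_dir, gzip = FALSE, in_disk = FALSE) {
    op <- make_op(params)
    process_fileset(fileset, op, output_dir,
                    mode = if (in_disk) "on-disk" else "in-memory",
                    gzip = gzip)
  }
}

param_defaults <- function(desc, params) {
  for (o in desc$options) {
    if (is.null(params[[o$name]]) && !is.null(o$default))
      params[[o$name]] <- o$default
  }
  params
}

#' Execute a registered command over a file set
#'
#' Library-level entry point used by both the CLI and the pipeline engine:
#' applies the command's defaults to `params` and runs its executor.
#'
#' @param name command name.
#' @param fileset a `file_set`.
#' @param params named list of command-specific parameters (kebab-case
#'   names as in the CLI).
#' @param output_dir destination directory.
#' @param gzip gzip the outputs.
#' @param in_disk stream files one at a time.
#' @return list with `fileset` (outputs) and `errors`.
#' @export
execute_command <- function(name, fileset, params, output_dir,
                            gzip = FALSE, in_disk = FALSE) {
  desc <- get_command(name)
  validate_config_names(name, names(params))
  params <- param_defaults(desc, params)
  desc$executor(fileset, params, output_dir, gzip = gzip, in_disk = in_disk)
}

int_or_null <- function(x) if (is.null(x)) NULL else as.numeric(x)

populate_registry <- function() {
  register_command(
    "filter-by-length", "Keep records by sequence-length bounds",
    list(opt("min-length", "min", "int", NULL, "Inclusive minimum length"),
         opt("max-length", "max", "int", NULL, "Inclusive maximum length"),
         opt("keep", NULL, "str", "inside",
             "Keep records 'inside' or 'outside' the bounds")),
    dataset_executor(function(p) function(d)
      filter_by_length(d, int_or_null(p[["min-length"]]),
                       int_or_null(p[["max-length"]]), keep = p$keep)))

  register_command(
    "filter-by-pattern", "Keep records matching a regular expression",
    list(opt("pattern", "p", "str", NULL, "Regular expression (required)"),
         opt("target", NULL, "str", "header",
             "Match against 'header' or 'sequence'"),
         opt("case-insensitive", "i", "flag", FALSE,
             "Match case-insensitively"),
         opt("keep", NULL, "str", "match", "Keep 'match' or 'no-match'")),
    dataset_executor(function(p) function(d) {
      if (is.null(p$pattern)) usage_error("filter-by-pattern requires --pattern")
      filter_by_pattern(d, p$pattern, target = p$target,
                        case_sensitive = !isTRUE(p[["case-insensitive"]]),
                        keep = p$keep)
    }))

  register_command(
    "sort-sequences", "Sort records by length, header or residues",
    list(opt("by", NULL, "str", "length",
             "Sort key: 'length', 'header' or 'sequence'"),
         opt("descending", "r", "flag", FALSE, "Reverse the order")),
    dataset_executor(function(p) function(d)
      sort_sequences(d, by = p$by, descending = isTRUE(p$descending))))

  register_command(
    "edit-headers", "Edit record headers",
    list(opt("mode", NULL, "str", "number",
             "One of add-prefix, add-suffix, replace, number"),
         opt("text", NULL, "str", NULL, "Affix or replacement text"),
         opt("find", NULL, "str", NULL, "Substring to replace (mode replace)"),
         opt("separator", NULL, "str", "_", "Affix separator")),
    dataset_executor(function(p) function(d)
      edit_headers(d, mode = p$mode, text = p$text, find = p$find,
                   separator = p$separator)))

  register_command(
    "reverse-complement", "Reverse and/or complement nucleotide records",
    list(opt("reverse", NULL, "bool", TRUE, "Reverse the sequences"),
         opt("complement", NULL, "bool", TRUE, "Complement the sequences")),
    dataset_executor(function(p) function(d)
      reverse_complement(d, reverse = isTRUE(p$reverse),
                         complement = isTRUE(p$complement))))

  register_command(
    "translate", "Translate nucleotide records to protein",
    list(opt("frame", "f", "int", 1L, "Reading frame (1-3)"),
         opt("reverse-strand", NULL, "flag", FALSE,
             "Translate the reverse complement")),
    dataset_executor(function(p) function(d)
      translate_sequences(d, frame = as.integer(p$frame),
                          use_reverse_strand = isTRUE(p[["reverse-strand"]]))))

  register_command(
    "remove-isoforms", "Keep one representative per header-word group",
    list(opt("min-word-length", NULL, "int", 5L,
             "Minimum shared-word length for grouping"),
         opt("reference-size", NULL, "int", 0L,
             "Keep the record with length closest to this value")),
    dataset_executor(function(p) function(d)
      remove_isoforms(d, min_word_length = as.integer(p[["min-word-length"]]),
                      reference_size = as.integer(p[["reference-size"]]))))

  register_command(
    "deduplicate", "Remove duplicate records (first occurrence kept)",
    list(opt("by", NULL, "str", "exact-sequence",
             "Duplicate key: 'exact-sequence' or 'id'")),
    dataset_executor(function(p) function(d) deduplicate(d, by = p$by)))

  register_command(
    "merge-datasets", "Concatenate all input files into one dataset",
    list(opt("output-name", NULL, "str", "merged.fasta",
             "Name of the merged output file")),
    function(fileset, params, output_dir, gzip = FALSE, in_disk = FALSE) {
      dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
      merged <- merge_datasets(fileset)
      path <- write_fasta(merged, file.path(output_dir, params[["output-name"]]),
                          gzip = gzip)
      list(fileset = new_fileset(path, "explicit-files"), errors = list())
    })

  register_command(
    "split-dataset", "Split each input file into several files",
    list(opt("per-file", NULL, "int", NULL, "Records per output file"),
         opt("parts", NULL, "int", NULL, "Number of output files"),
         opt("prefix", NULL, "str", NULL,
             "Output basename prefix (default: input basename)")),
    function(fileset, params, output_dir, gzip = FALSE, in_disk = FALSE) {
      dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
      outs <- character(); errors <- list()
      for (p in fileset$paths) {
        res <- tryCatch({
          d <- read_fasta(p)
          prefix <- params$prefix %||%
            sub("\\.[^.]*$", "", sub("\\.gz$", "", basename(p)))
          split_dataset(d, output_dir,
                        per_file = int_or_null(params[["per-file"]]),
                        parts = int_or_null(params$parts),
                        prefix = prefix, gzip = gzip)$paths
        }, error = function(e) e)
        if (inherits(res, "error")) errors[[p]] <- conditionMessage(res)
        else outs <- c(outs, res)
      }
      list(fileset = new_fileset(outs, "explicit-files"), errors = errors)
    })

  register_command(
    "cga", "Conserved-gene annotation of genomic regions",
    list(opt("reference", NULL, "str", NULL,
             "FASTA file with the single reference protein (required)"),
         opt("min-orf-length", NULL, "int", 30L,
             "Report ORFs strictly longer than this many nucleotides"),
         opt("e-value", NULL, "num", 0.05,
             "Significance threshold for reference matches"),
         opt("min-cds-size", NULL, "int", 30L,
             "Minimum predicted-CDS length in nucleotides"),
         opt("junction-window", NULL, "int", 30L,
             "Splice-junction search half-width in nucleotides")),
    function(fileset, params, output_dir, gzip = FALSE, in_disk = FALSE) {
      if (is.null(params$reference))
        usage_error("cga requires --reference")
      errors <- list()
      for (p in fileset$paths) {
        res <- tryCatch(
          run_cga(p, params$reference, output_dir,
                  min_orf_length = as.integer(params[["min-orf-length"]]),
                  e_value = as.numeric(params[["e-value"]]),
                  min_cds_size = as.integer(params[["min-cds-size"]]),
                  junction_window = as.integer(params[["junction-window"]])),
          error = function(e) e)
        if (inherits(res, "error")) errors[[p]] <- conditionMessage(res)
      }
      outs <- list.files(output_dir, recursive = TRUE, full.names = TRUE)
      list(fileset = new_fileset(outs, "explicit-files"), errors = errors)
    })
}
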