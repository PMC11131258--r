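# Convention-based pipeline engine: a declarative task graph over toolkit
# commands. Task ids are command names (optionally disambiguated with a
# trailing _<digits> suffix); initial tasks read input/<task_id>/, dependent
# tasks read the union of output/<predecessor>/ directories, and
# input/lists/<task_id>.txt overrides either; parameters come from
# params/<task_id>.sedaParams (JSON) or params/<task_id>.cliParams (one
# line of CLI arguments); outputs land in output/<task_id>/. Tasks whose
# XML element carries text run that text as a shell command instead of a
# toolkit command.

task_command <- function(id) sub("_[0-9]+$", "", id)

new_taskspec <- function(id, after = character(), batch_size = "all",
                         foreign_command = NULL) {
  structure(list(id = id, after = after, batch_size = batch_size,
                 foreign_command = foreign_command),
            class = "task_spec")
}

#' Parse a pipeline description file
#'
#' XML layout (a small convention-based dialect):
#' `<pipeline><params><param name="...">value</param></params>`
#' `<tasks><task id="..." after="dep1 dep2" batchSize="3"/>...</tasks></pipeline>`.
#' A `<task>` element with non-empty text content is a foreign task whose
#' text is run as a shell command. A YAML front-end with identical
#' semantics is accepted for files ending `.yml`/`.yaml` (keys `params` and
#' `tasks`, each task a map with `id`, `after`, `batch_size`, `run`).
#'
#' @param path path to the pipeline file.
#' @return a `pipeline_spec`: list with `parameters` and `tasks`.
#' @export
parse_pipeline <- function(path) {
  if (!file.exists(path)) input_error(sprintf("pipeline file '%s' not found", path))
  spec <- if (grepl("\\.ya?ml$", path)) parse_pipeline_yaml(path)
          else parse_pipeline_xml(path)
  validate_pipeline(spec)
  spec
}

parse_pipeline_xml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e)
                    format_error(sprintf("'%s' is not well-formed XML: %s",
                                         path, conditionMessage(e))))
  params <- list()
  for (p in xml2::xml_find_all(doc, "./params/param")) {
    params[[xml2::xml_attr(p, "name")]] <- xml2::xml_text(p)
  }
  tasks <- lapply(xml2::xml_find_all(doc, "./tasks/task"), function(t) {
    id <- xml2::xml_attr(t, "id")
    if (is.na(id) || !nzchar(id)) format_error("task without an id attribute")
    after <- xml2::xml_attr(t, "after")
    after <- if (is.na(after)) character()
             else strsplit(trimws(after), "[,[:space:]]+")[[1]]
    bs <- xml2::xml_attr(t, "batchSize")
    bs <- if (is.na(bs) || bs == "all") "all" else as.integer(bs)
    body <- trimws(xml2::xml_text(t))
    new_taskspec(id, after, bs, if (nzchar(body)) body else NULL)
  })
  structure(list(parameters = params, tasks = tasks), class = "pipeline_spec")
}

parse_pipeline_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  tasks <- lapply(y$tasks, function(t) {
    bs <- t$batch_size %||% "all"
    if (!identical(bs, "all")) bs <- as.integer(bs)
    new_taskspec(t$id, as.character(t$after %||% character()), bs,
                 t$run %||% NULL)
  })
  structure(list(parameters = y$params %||% list(), tasks = tasks),
            class = "pipeline_spec")
}

validate_pipeline <- function(spec) {
  ids <- vapply(spec$tasks, `[[`, character(1), "id")
  if (length(ids) == 0L) usage_error("pipeline defines no tasks")
  if (anyDuplicated(ids))
    usage_error(sprintf("duplicate task id '%s'", ids[duplicated(ids)][1]))
  for (t in spec$tasks) {
    missing <- setdiff(t$after, ids)
    if (length(missing))
      usage_error(sprintf("task '%s' depends on undefined task '%s'",
                          t$id, missing[1]))
    if (is.null(t$foreign_command) &&
        !task_command(t$id) %in% list_commands())
      usage_error(sprintf("task '%s' is not a registered command (and has no shell body)",
                          t$id))
    if (!identical(t$batch_size, "all") &&
        (is.na(t$batch_size) || t$batch_size < 1))
      usage_error(sprintf("task '%s': batchSize must be a positive integer or \"all\"",
                          t$id))
  }
  topo_order(spec)  # errors on cycles
  invisible(spec)
}

# Kahn topological sort, deterministic: ready tasks run in definition order.
topo_order <- function(spec) {
  ids <- vapply(spec$tasks, `[[`, character(1), "id")
  after <- lapply(spec$tasks, `[[`, "after")
  names(after) <- ids
  done <- character()
  order <- character()
  remaining <- ids
  while (length(remaining)) {
    ready <- remaining[vapply(remaining, function(i)
      all(after[[i]] %in% done), logical(1))]
    if (length(ready) == 0L)
      usage_error(sprintf("pipeline contains a dependency cycle involving: %s",
                          paste(remaining, collapse = ", ")))
    order <- c(order, ready)
    done <- c(done, ready)
    remaining <- setdiff(remaining, ready)
  }
  order
}

#' Resolve a task's input files
#'
#' `input/lists/<task_id>.txt` (paths relative to the workspace root)
#' overrides everything; otherwise tasks without dependencies read
#' `input/<task_id>/` and dependent tasks read the union of
#' `output/<predecessor>/` for every predecessor. An empty resolved set is
#' an error (fail fast, before execution).
#'
#' @param task a task of a parsed pipeline.
#' @param workspace_root workspace directory.
#' @return a `file_set`.
#' @export
resolve_task_inputs <- function(task, workspace_root) {
  listfile <- file.path(workspace_root, "input", "lists",
                        paste0(task$id, ".txt"))
  fs <- if (file.exists(listfile)) {
    lines <- trimws(sub("\r$", "", readLines(listfile, warn = FALSE)))
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    paths <- ifelse(grepl("^/", lines), lines,
                    file.path(workspace_root, lines))
    # also accept paths already relative to the workspace input dir
    missing <- !file.exists(paths)
    paths[missing] <- lines[missing]
    bad <- paths[!file.exists(paths)]
    if (length(bad))
      input_error(sprintf("task '%s': list references missing path '%s'",
                          task$id, bad[1]))
    new_fileset(unique(paths), "list-file")
  } else if (length(task$after) == 0L) {
    resolve_inputs(input_directory = file.path(workspace_root, "input", task$id))
  } else {
    paths <- unlist(lapply(task$after, function(p) {
      dir <- file.path(workspace_root, "output", p)
      if (!dir.exists(dir))
        input_error(sprintf("task '%s': predecessor output directory '%s' missing",
                            task$id, dir))
      resolve_inputs(input_directory = dir)$paths
    }))
    new_fileset(unique(paths), "directory")
  }
  if (length(fs$paths) == 0L)
    input_error(sprintf("task '%s': no input files resolved", task$id))
  fs
}

#' Resolve a task's parameters
#'
#' `params/<task_id>.sedaParams` (a JSON parameter file for the task's
#' command) is preferred; `params/<task_id>.cliParams` holds one line of
#' standard CLI arguments; both present is an error; neither means command
#' defaults.
#'
#' @param task a task of a parsed pipeline.
#' @param workspace_root workspace directory.
#' @return list with `source` (`"sedaParams"`, `"cliParams"` or
#'   `"defaults"`), `params` (named list) and `path`.
#' @export
resolve_task_params <- function(task, workspace_root) {
  sp <- file.path(workspace_root, "params", paste0(task$id, ".sedaParams"))
  cp <- file.path(workspace_root, "params", paste0(task$id, ".cliParams"))
  if (file.exists(sp) && file.exists(cp))
    usage_error(sprintf("task '%s': both .sedaParams and .cliParams present", task$id))
  if (file.exists(sp)) {
    cfg <- load_parameters(sp, expected_command = task_command(task$id))
    return(list(source = "sedaParams", params = cfg$parameters, path = sp))
  }
  if (file.exists(cp)) {
    line <- paste(readLines(cp, warn = FALSE), collapse = " ")
    argv <- strsplit(trimws(line), "[[:space:]]+")[[1]]
    argv <- argv[nzchar(argv)]
    params <- parse_specific_args(task_command(task$id), argv)
    return(list(source = "cliParams", params = params, path = cp))
  }
  list(source = "defaults", params = list(), path = NULL)
}

#' Execute a pipeline over a workspace
#'
#' Tasks run in a deterministic topological order of the dependency graph.
#' Each task's inputs are split into batches of `batchSize` files and the
#' command runs once per batch into `output/<task_id>/`. Foreign tasks run
#' their shell command once per batch with `INPUT_DIR` (a staging directory
#' holding the batch files), `OUTPUT_DIR` and `WORKSPACE` in the
#' environment. A failed task marks its descendants `failed-upstream` but
#' independent branches still run. With `resume = TRUE`, tasks whose output
#' directory already exists and is non-empty are skipped. Per-task logs and
#' a pipeline summary are written under `logs/`.
#'
#' @param spec a `pipeline_spec` from [parse_pipeline()], or a path.
#' @param workspace_root workspace directory.
#' @param dry_run print the execution plan without running anything.
#' @param resume skip tasks with existing non-empty output.
#' @return invisibly, a data frame of task runs: `id`, `status`
#'   (`done` / `failed` / `failed-upstream` / `skipped` / `planned`),
#'   `n_inputs`, `n_batches`, `params_source`, `seconds`.
#' @export
execute_pipeline <- function(spec, workspace_root, dry_run = FALSE,
                             resume = FALSE) {
  if (is.character(spec)) spec <- parse_pipeline(spec)
  order <- topo_order(spec)
  tasks <- spec$tasks
  names(tasks) <- vapply(tasks, `[[`, character(1), "id")
  logdir <- file.path(workspace_root, "logs")
  dir.create(logdir, showWarnings = FALSE, recursive = TRUE)
  plog <- file.path(logdir, "pipeline.log")
  note <- function(...) cat(sprintf("[%s] %s\n", format(Sys.time(), "%H:%M:%OS3"),
                                    sprintf(...)),
                            file = plog, append = TRUE)
  status <- stats::setNames(rep("pending", length(tasks)), names(tasks))
  rows <- list()
  for (id in order) {
    task <- tasks[[id]]
    t0 <- Sys.time()
    run <- list(id = id, status = "planned", n_inputs = NA_integer_,
                n_batches = NA_integer_, params_source = NA_character_,
                seconds = NA_real_)
    outdir <- file.path(workspace_root, "output", id)
    if (any(status[task$after] %in% c("failed", "failed-upstream"))) {
      status[id] <- "failed-upstream"
      note("task %s: skipped, upstream failure", id)
      run$status <- "failed-upstream"
      rows[[id]] <- run
      next
    }
    if (resume && dir.exists(outdir) && length(list.files(outdir)) > 0) {
      status[id] <- "done"
      note("task %s: resume, output already present", id)
      run$status <- "skipped"
      rows[[id]] <- run
      next
    }
    res <- tryCatch({
      inputs <- if (dry_run && length(task$after))
        tryCatch(resolve_task_inputs(task, workspace_root),
                 ff_error = function(e) new_fileset(character(), "directory"))
      else resolve_task_inputs(task, workspace_root)
      pars <- resolve_task_params(task, workspace_root)
      batches <- split_batches(inputs$paths, task$batch_size)
      run$n_inputs <- length(inputs$paths)
      run$n_batches <- length(batches)
      run$params_source <- pars$source
      if (dry_run) {
        note("plan %s: %d file(s) in %d batch(es), params from %s",
             id, length(inputs$paths), length(batches), pars$source)
        "planned"
      } else {
        dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
        tlog <- file.path(logdir, paste0(id, ".log"))
        for (b in seq_along(batches)) {
          run_task_batch(task, batches[[b]], pars, outdir, workspace_root,
                         tlog, b)
        }
        note("task %s: done (%d batch(es))", id, length(batches))
        "done"
      }
    }, error = function(e) {
      note("task %s: FAILED: %s", id, conditionMessage(e))
      "failed"
    })
    status[id] <- if (res == "planned") "done" else res
    run$status <- res
    run$seconds <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    rows[[id]] <- run
  }
  out <- do.call(rbind, lapply(rows[order], function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  if (any(out$status %in% c("failed", "failed-upstream")))
    attr(out, "exit_status") <- 3L else attr(out, "exit_status") <- 0L
  invisible(out)
}

split_batches <- function(paths, batch_size) {
  if (identical(batch_size, "all") || batch_size >= length(paths))
    return(list(paths))
  split(paths, ceiling(seq_along(paths) / batch_size))
}

run_task_batch <- function(task, batch, pars, outdir, workspace_root,
                           tlog, batch_no) {
  stamp <- function(...) cat(sprintf("[%s] batch %d: %s\n",
                                     format(Sys.time(), "%H:%M:%OS3"),
                                     batch_no, sprintf(...)),
                             file = tlog, append = TRUE)
  if (!is.null(task$foreign_command)) {
    staging <- file.path(tempdir(), sprintf("ff_stage_%s_%d", task$id, batch_no))
    unlink(staging, recursive = TRUE)
    dir.create(staging, recursive = TRUE)
    file.copy(batch, staging)
    stamp("foreign: %s", task$foreign_command)
    out <- suppressWarnings(system2("bash", c("-c", shQuote(task$foreign_command)),
                                    stdout = TRUE, stderr = TRUE,
                                    env = c(paste0("INPUT_DIR=", staging),
                                            paste0("OUTPUT_DIR=", normalizePath(outdir)),
                                            paste0("WORKSPACE=", normalizePath(workspace_root)))))
    code <- attr(out, "status") %||% 0L
    if (length(out)) stamp("output: %s", paste(out, collapse = " | "))
    if (code != 0L)
      processing_error(sprintf("foreign task '%s' exited with status %d",
                               task$id, code))
    return(invisible())
  }
  cmd <- task_command(task$id)
  stamp("command %s on %d file(s)", cmd, length(batch))
  res <- execute_command(cmd, new_fileset(batch, "explicit-files"),
                         pars$params, outdir)
  if (length(res$errors))
    processing_error(sprintf("command '%s' failed on %d file(s): %s", cmd,
                             length(res$errors), res$errors[[1]]))
  invisible()
}
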