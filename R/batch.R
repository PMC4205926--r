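#' Run a batch of simulation tasks
#'
#' Dispatches independent tasks over a process pool (forked workers) and
#' collects results in task order regardless of completion order; the
#' worker count never affects the values, only the wall time.  A failing
#' task yields a structured failure record and the batch continues.
#'
#' @param tasks list of `simulation_task`s from [expand_tasks()].
#' @param plugin [model_plugin()] executing each task.
#' @param workers process count, `>= 1`.
#' @return list, same length/order as `tasks`: each element either the
#'   task's time-series result (with `task_id` attribute) or a
#'   `task_failure` record `list(task_id, error)`.
#' @export
run_batch <- function(tasks, plugin, workers = 1) {
  stopifnot(inherits(plugin, "model_plugin"), workers >= 1)
  if (!length(tasks)) return(list())
  run1 <- function(task) {
    tryCatch({
      res <- plugin$entry(task$assignment, task$protocol, task$output_spec)
      attr(res, "task_id") <- task$task_id
      res
    }, error = function(e)
      structure(list(task_id = task$task_id, error = conditionMessage(e)),
                class = "task_failure"))
  }
  if (workers == 1 || .Platform$OS.type == "windows")
    lapply(tasks, run1)
  else
    parallel::mclapply(tasks, run1, mc.cores = workers,
                       mc.preschedule = FALSE)
}

#' Persist batch results as text files plus a manifest
#'
#' One CSV per task (`time` column first) and a JSON manifest mapping task
#' id to file, row count and content checksum.  [load_results()] verifies
#' the checksums and reloads losslessly to the written precision.
#'
#' @param results list from [run_batch()].
#' @param directory output directory (created if needed).
#' @return path of the manifest file, invisibly.
#' @export
store_results <- function(results, directory) {
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  entries <- list()
  for (i in seq_along(results)) {
    r <- results[[i]]
    if (inherits(r, "task_failure")) {
      entries[[i]] <- list(task_id = r$task_id, file = NA, error = r$error)
      next
    }
    id <- attr(r, "task_id") %||% sprintf("task%03d", i)
    file <- sprintf("result_%s.csv", id)
    path <- file.path(directory, file)
    utils::write.csv(format(as.data.frame(r), digits = 15, trim = TRUE,
                            scientific = FALSE),
                     path, row.names = FALSE, quote = FALSE)
    entries[[i]] <- list(task_id = id, file = file, rows = nrow(r),
                         checksum = .content_hash(readLines(path)))
  }
  manifest <- file.path(directory, "manifest.json")
  jsonlite::write_json(entries, manifest, auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' @rdname store_results
#' @param manifest path to a manifest written by [store_results()].
#' @return `load_results`: list of data.frames (or failure records), in
#'   manifest order.
#' @export
load_results <- function(manifest) {
  entries <- jsonlite::read_json(manifest)
  directory <- dirname(manifest)
  lapply(entries, function(e) {
    if (is.null(e$file) || is.na(e$file) || !is.null(e$error))
      return(structure(list(task_id = e$task_id, error = e$error),
                       class = "task_failure"))
    path <- file.path(directory, e$file)
    if (!file.exists(path))
      stop("integrity error: missing result file for task ", e$task_id,
           call. = FALSE)
    if (!identical(.content_hash(readLines(path)), e$checksum))
      stop("integrity error: checksum mismatch for task ", e$task_id,
           call. = FALSE)
    res <- utils::read.csv(path)
    attr(res, "task_id") <- e$task_id
    res
  })
}
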