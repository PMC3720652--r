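#' Define a scatter/gather plugin
#'
#' A plugin is the unit of work the execution engine schedules over byte
#' chunks of a large input. It mirrors the four shell functions a cluster
#' pipeline plugin implements: planning the split, counting chunks,
#' processing one chunk, and combining part results.
#'
#' @param process_chunk `function(input, start, end)` returning the part
#'   result for the inclusive byte range `[start, end]` of `input`.
#' @param combine `function(parts)` merging an ordered list of part results
#'   into the complete result. Must be identity on a singleton list.
#' @param plan_split Optional `function(input, chunk_size)` returning a
#'   [compute_chunk_plan()] plan; the default plans over `file.size(input)`.
#' @param count_chunks Optional `function(plan)`; defaults to `plan$n_tasks`.
#' @return A `goby_plugin` object.
#' @export
goby_plugin <- function(process_chunk, combine,
                        plan_split = NULL, count_chunks = NULL) {
  stopifnot(is.function(process_chunk), is.function(combine))
  if (is.null(plan_split))
    plan_split <- function(input, chunk_size)
      compute_chunk_plan(file.size(input), chunk_size)
  if (is.null(count_chunks))
    count_chunks <- function(plan) plan$n_tasks
  structure(
    list(plan_split = plan_split, count_chunks = count_chunks,
         process_chunk = process_chunk, combine = combine),
    class = "goby_plugin"
  )
}

#' Run a plugin over an input file with array-job semantics
#'
#' Plans byte chunks, executes `process_chunk` for every chunk on a local
#' worker pool, then gathers: `combine` is invoked on the parts of all
#' *completed* tasks in task order, even when some tasks failed, so a run
#' with partial failures still produces an output for the data that could
#' be processed. Failed tasks are flagged in the per-task results and the
#' status log; only if every task fails is the run itself marked failed.
#'
#' @param plugin A [goby_plugin].
#' @param input Path to the input file.
#' @param workers Number of parallel workers (forked; 1 = sequential).
#' @param chunk_size Chunk size in bytes.
#' @param tag Run tag for the status log; default a fresh [make_tag()].
#' @param log_dir Directory for the status log.
#' @return A list with elements
#'   \describe{
#'     \item{result}{the combined result over completed chunks (`NULL` if
#'       every chunk failed)}
#'     \item{tasks}{data.frame of per-task results: `task_id`, `status`
#'       (`"completed"`/`"failed"`), `diagnostics`}
#'     \item{parts}{list of part results of completed tasks, by task order}
#'     \item{status}{`"completed"` or `"failed"` (all chunks failed)}
#'     \item{log}{the [status_log] used}
#'   }
#' @export
run_parallel <- function(plugin, input, workers = 1L,
                         chunk_size = DEFAULT_CHUNK_SIZE,
                         tag = make_tag(), log_dir = tempdir()) {
  stopifnot(inherits(plugin, "goby_plugin"))
  log <- status_log(tag, log_dir)
  log_event(log, "submitted", sprintf("input=%s chunk_size=%g", input, chunk_size))
  if (!file.exists(input) || file.access(input, 4L) != 0L) {
    log_event(log, "failed", sprintf("input not readable: %s", input))
    stop("input not readable: ", input)
  }
  plan <- plugin$plan_split(input, chunk_size)
  n <- plugin$count_chunks(plan)
  log_event(log, "started", sprintf("n_tasks=%d workers=%d", n, workers))

  run_one <- function(i) {
    bounds <- plan$tasks[i, ]
    tryCatch(
      list(status = "completed",
           payload = plugin$process_chunk(input, bounds$start, bounds$end),
           diagnostics = ""),
      error = function(e)
        list(status = "failed", payload = NULL,
             diagnostics = conditionMessage(e))
    )
  }

  outcomes <- if (n == 0L) {
    list()
  } else if (workers > 1L && .Platform$OS.type == "unix") {
    parallel::mclapply(seq_len(n), run_one, mc.cores = workers)
  } else {
    lapply(seq_len(n), run_one)
  }

  statuses <- vapply(outcomes, `[[`, "", "status")
  for (i in seq_len(n)) {
    log_event(log, "step",
              sprintf("task %d/%d %s%s", i, n, statuses[i],
                      if (statuses[i] == "failed")
                        paste0(": ", outcomes[[i]]$diagnostics) else ""))
  }
  tasks <- data.frame(
    task_id = seq_len(n),
    status = if (n) statuses else character(),
    diagnostics = if (n) vapply(outcomes, `[[`, "", "diagnostics")
                  else character(),
    stringsAsFactors = FALSE
  )
  completed <- which(statuses == "completed")
  parts <- lapply(outcomes[completed], `[[`, "payload")

  if (n > 0L && length(completed) == 0L) {
    log_event(log, "failed", "all chunks failed")
    return(list(result = NULL, tasks = tasks, parts = parts,
                status = "failed", log = log))
  }
  result <- plugin$combine(parts)
  log_event(log, "completed",
            sprintf("%d/%d tasks completed", length(completed), n))
  list(result = result, tasks = tasks, parts = parts,
       status = "completed", log = log)
}

#' Recursively concatenate part files, bounding open handles
#'
#' Concatenates `parts` (file paths) into `dest` in order, combining at
#' most `fan_in` pieces at a time and recursing over the intermediate
#' merges, so that no more than `fan_in` parts are ever open
#' simultaneously. The output is byte-identical to a direct single-pass
#' concatenation; the recursion only exists to bound file handles when
#' gathering hundreds of chunk outputs.
#'
#' @param parts Non-empty character vector of file paths, in merge order.
#' @param dest Destination file path.
#' @param fan_in Maximum number of pieces combined per pass (>= 2),
#'   default 100.
#' @return `dest`, invisibly.
#' @export
recursive_concat <- function(parts, dest, fan_in = 100L) {
  if (length(parts) == 0L) stop("parts must be non-empty")
  if (fan_in < 2L) stop("fan_in must be >= 2")
  if (length(parts) == 1L) {
    file.copy(parts, dest, overwrite = TRUE)
    return(invisible(dest))
  }
  concat_batch <- function(files, out) {
    con <- file(out, "wb")
    on.exit(close(con))
    for (f in files) {
      src <- file(f, "rb")
      repeat {
        buf <- readBin(src, "raw", n = 1024L * 1024L)
        if (length(buf) == 0L) break
        writeBin(buf, con)
      }
      close(src)
    }
    out
  }
  level <- parts
  tmps <- character()
  on.exit(unlink(tmps), add = TRUE)
  while (length(level) > fan_in) {
    groups <- split(level, ceiling(seq_along(level) / fan_in))
    level <- vapply(groups, function(g) {
      out <- tempfile("concat-")
      tmps <<- c(tmps, out)
      concat_batch(g, out)
    }, character(1))
  }
  concat_batch(level, dest)
  invisible(dest)
}
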