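#' Default chunk size for array-job splitting (bytes)
#'
#' Large read files are split into byte-range chunks of approximately 50 MB
#' each; every chunk becomes one task of an emulated array job.
#' @export
DEFAULT_CHUNK_SIZE <- 50e6

#' Plan byte-offset chunks over an input file
#'
#' Decomposes a file of `file_size` bytes into `ceiling(file_size /
#' chunk_size)` tasks. Task `i` (1-based) covers the inclusive byte range
#' `[(i - 1) * chunk_size, i * chunk_size - 1]`; the final task's end offset
#' is clamped to `file_size - 1`.
#'
#' @param file_size Non-negative file size in bytes.
#' @param chunk_size Positive chunk size in bytes; default
#'   [DEFAULT_CHUNK_SIZE] (50,000,000).
#' @return An object of class `chunk_plan`: a list with `file_size`,
#'   `chunk_size`, `n_tasks` and a `data.frame` `tasks` with columns
#'   `task_id`, `start`, `end`.
#' @examples
#' plan <- compute_chunk_plan(30 * 2^30)   # a 30 GiB reads file
#' plan$n_tasks                            # 645 chunks
#' @export
compute_chunk_plan <- function(file_size, chunk_size = DEFAULT_CHUNK_SIZE) {
  file_size <- as.numeric(file_size)
  chunk_size <- as.numeric(chunk_size)
  if (length(chunk_size) != 1L || is.na(chunk_size) || chunk_size <= 0)
    stop("chunk_size must be a positive number of bytes")
  if (length(file_size) != 1L || is.na(file_size) || file_size < 0)
    stop("file_size must be a non-negative number of bytes")
  n_tasks <- ceiling(file_size / chunk_size)
  if (n_tasks == 0) {
    tasks <- data.frame(task_id = integer(), start = numeric(),
                        end = numeric())
  } else {
    task_id <- seq_len(n_tasks)
    start <- (task_id - 1) * chunk_size
    end <- pmin(start + chunk_size - 1, file_size - 1)
    tasks <- data.frame(task_id = task_id, start = start, end = end)
  }
  structure(
    list(file_size = file_size, chunk_size = chunk_size,
         n_tasks = n_tasks, tasks = tasks),
    class = "chunk_plan"
  )
}

#' @export
print.chunk_plan <- function(x, ...) {
  cat(sprintf("chunk_plan: %s bytes in %d task(s) of %s bytes\n",
              format(x$file_size, big.mark = ","), x$n_tasks,
              format(x$chunk_size, big.mark = ",")))
  invisible(x)
}

#' Byte bounds of one array-job task
#'
#' The start offset is `(task_id - 1) * chunk_size` and the end offset
#' `start + chunk_size - 1` (inclusive), mirroring how an array-job task
#' index is mapped to a slice of the reads file.
#'
#' @param task_id 1-based task index.
#' @param chunk_size Chunk size in bytes.
#' @return Named numeric vector with elements `start` and `end`.
#' @examples
#' chunk_bounds(1, 50e6)  # c(start = 0, end = 49999999)
#' @export
chunk_bounds <- function(task_id, chunk_size = DEFAULT_CHUNK_SIZE) {
  if (length(task_id) != 1L || is.na(task_id) || task_id < 1)
    stop("task_id must be >= 1")
  task_id <- as.numeric(task_id)
  chunk_size <- as.numeric(chunk_size)
  if (chunk_size <= 0) stop("chunk_size must be positive")
  start <- (task_id - 1) * chunk_size
  c(start = start, end = start + chunk_size - 1)
}
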