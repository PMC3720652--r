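#' Open a JSON-lines status log for a run
#'
#' Every pipeline run is identified by a short run tag and reports its
#' lifecycle (submitted, started, per-task steps, failed, completed) as
#' append-only JSON-lines events, one object per line. This stands in for
#' the status-posting side channel a cluster deployment would use.
#'
#' @param tag Run tag (see [make_tag]).
#' @param dir Directory in which to create `<tag>.status.jsonl`.
#' @return A `status_log` object (list with `tag` and `path`).
#' @export
status_log <- function(tag, dir = tempdir()) {
  stopifnot(is.character(tag), length(tag) == 1L)
  path <- file.path(dir, paste0(tag, ".status.jsonl"))
  if (!file.exists(path)) file.create(path)
  structure(list(tag = tag, path = path), class = "status_log")
}

#' Append an event to a status log
#'
#' @param log A [status_log] object.
#' @param phase One of `"submitted"`, `"started"`, `"step"`, `"failed"`,
#'   `"completed"`.
#' @param message Free-text message.
#' @return The log, invisibly.
#' @export
log_event <- function(log, phase, message = "") {
  phase <- match.arg(phase,
                     c("submitted", "started", "step", "failed", "completed"))
  event <- list(
    run_tag = log$tag,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%OS6%z"),
    phase = phase,
    message = message
  )
  line <- jsonlite::toJSON(event, auto_unbox = TRUE)
  cat(line, "\n", sep = "", file = log$path, append = TRUE)
  invisible(log)
}

#' Read back all events of a status log
#'
#' @param log A [status_log] object or a path to a `.status.jsonl` file.
#' @return data.frame with columns `run_tag`, `timestamp`, `phase`,
#'   `message`, in append order.
#' @export
read_status_log <- function(log) {
  path <- if (inherits(log, "status_log")) log$path else log
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L)
    return(data.frame(run_tag = character(), timestamp = character(),
                      phase = character(), message = character()))
  events <- lapply(lines, jsonlite::fromJSON)
  data.frame(
    run_tag = vapply(events, `[[`, "", "run_tag"),
    timestamp = vapply(events, `[[`, "", "timestamp"),
    phase = vapply(events, `[[`, "", "phase"),
    message = vapply(events, `[[`, "", "message"),
    stringsAsFactors = FALSE
  )
}
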