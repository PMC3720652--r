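# Byte-offset record semantics for text FASTQ/SAM: a record belongs to the
# chunk containing its first byte. Workers seek to the chunk start, scan
# forward to the first record boundary, and stop at the first record whose
# first byte lies beyond the chunk end, so chunk record sets partition the
# file with no duplication.

# Lines of `path` from absolute byte offset `from` to EOF, with the
# absolute byte offset of each line start. Unix line endings assumed.
.lines_from <- function(path, from) {
  fsize <- file.size(path)
  if (is.na(fsize)) stop("cannot stat file: ", path)
  if (from >= fsize) return(list(lines = character(), offsets = numeric()))
  con <- file(path, "rb")
  on.exit(close(con))
  seek(con, from)
  raw <- readBin(con, "raw", n = fsize - from)
  lines <- strsplit(rawToChar(raw), "\n", fixed = TRUE)[[1]]
  offsets <- from + cumsum(c(0, nchar(lines, "bytes") + 1))[seq_along(lines)]
  list(lines = lines, offsets = offsets)
}

# TRUE if `offset` starts a line (offset 0, or preceded by a newline).
.at_line_start <- function(path, offset) {
  if (offset <= 0) return(TRUE)
  con <- file(path, "rb")
  on.exit(close(con))
  seek(con, offset - 1)
  identical(readBin(con, "raw", 1L), as.raw(10L))
}

#' Extract the records of one byte chunk of a FASTQ or SAM file
#'
#' A record belongs to the chunk containing its first byte. Scanning starts
#' at `start`: a partial line is skipped (it belongs to the previous
#' chunk), then for FASTQ the four-line record phase is located, and
#' records are collected while their first byte offset is at most `end`.
#' Records may extend past `end`; they are read to completion. The union of
#' records over all chunks of a plan is exactly the file's records, each
#' appearing once.
#'
#' @param path FASTQ or SAM file (plain text, LF line endings).
#' @param start,end Inclusive byte range of the chunk.
#' @param format `"fastq"` (4-line records) or `"sam"` (one line per
#'   record; `@`-prefixed header lines are never records).
#' @return Character vector of records in file order; FASTQ records are the
#'   four lines joined with `"\n"`.
#' @export
assign_records_to_chunk <- function(path, start, end,
                                    format = c("fastq", "sam")) {
  format <- match.arg(format)
  region <- .lines_from(path, start)
  lines <- region$lines
  offsets <- region$offsets
  if (length(lines) == 0L) return(character())
  if (!.at_line_start(path, start)) {
    lines <- lines[-1L]
    offsets <- offsets[-1L]
  }
  keep <- offsets <= end
  if (format == "sam") {
    is_rec <- !startsWith(lines, "@")
    return(lines[keep & is_rec])
  }
  # FASTQ: find the 4-line phase. A record starts at a '@' line whose
  # third line is '+' and whose sequence/quality lengths agree; quality
  # lines can themselves start with '@', so the candidate must also be
  # consistent with the following record when one exists.
  phase_ok <- function(s) {
    if (s + 3L > length(lines)) return(FALSE)
    ok <- startsWith(lines[s], "@") && startsWith(lines[s + 2L], "+") &&
      nchar(lines[s + 1L]) == nchar(lines[s + 3L])
    if (!ok) return(FALSE)
    if (s + 7L <= length(lines)) {
      ok <- startsWith(lines[s + 4L], "@") &&
        startsWith(lines[s + 6L], "+") &&
        nchar(lines[s + 5L]) == nchar(lines[s + 7L])
    }
    ok
  }
  first <- NA_integer_
  for (s in 1:min(4L, length(lines))) {
    if (phase_ok(s)) { first <- s; break }
  }
  if (is.na(first))
    stop(sprintf("malformed FASTQ record near byte offset %.0f of %s",
                 offsets[1], path))
  records <- character()
  i <- first
  while (i <= length(lines) && offsets[i] <= end) {
    if (i + 3L > length(lines) || !startsWith(lines[i], "@") ||
        !startsWith(lines[i + 2L], "+") ||
        nchar(lines[i + 1L]) != nchar(lines[i + 3L]))
      stop(sprintf("malformed FASTQ record at byte offset %.0f of %s",
                   offsets[i], path))
    records <- c(records, paste(lines[i:(i + 3L)], collapse = "\n"))
    i <- i + 4L
  }
  records
}

#' Plugin that extracts chunk records
#'
#' Convenience [goby_plugin] whose `process_chunk` returns the chunk's
#' records via [assign_records_to_chunk] and whose `combine` concatenates
#' the per-chunk record vectors in task order.
#'
#' @param format `"fastq"` or `"sam"`.
#' @return A [goby_plugin].
#' @export
record_plugin <- function(format = c("fastq", "sam")) {
  format <- match.arg(format)
  goby_plugin(
    process_chunk = function(input, start, end)
      assign_records_to_chunk(input, start, end, format = format),
    combine = function(parts) do.call(c, c(parts, list(character())))
  )
}
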