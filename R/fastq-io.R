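#' Read a FASTQ file into a data.frame
#'
#' @param path FASTQ file (plain text or gzip).
#' @return data.frame with columns `id` (without the leading `@`), `seq`,
#'   `qual`.
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  if (length(lines) %% 4L != 0L)
    stop("FASTQ line count not a multiple of 4: ", path)
  n <- length(lines) %/% 4L
  if (n == 0L)
    return(data.frame(id = character(), seq = character(),
                      qual = character(), stringsAsFactors = FALSE))
  idx <- seq_len(n)
  heads <- lines[4L * idx - 3L]
  bad <- which(!startsWith(heads, "@"))
  if (length(bad))
    stop("malformed FASTQ record ", bad[1], " in ", path)
  data.frame(
    id = sub("^@", "", sub("\\s.*$", "", heads)),
    seq = lines[4L * idx - 2L],
    qual = lines[4L * idx],
    stringsAsFactors = FALSE
  )
}

#' Write a FASTQ file
#'
#' @param reads data.frame with columns `id`, `seq`, `qual`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(c("id", "seq", "qual") %in% names(reads)))
  if (nrow(reads) && any(nchar(reads$seq) != nchar(reads$qual)))
    stop("sequence and quality lengths differ")
  lines <- as.vector(rbind(paste0("@", reads$id), reads$seq, "+",
                           reads$qual))
  writeLines(lines, path)
  invisible(path)
}

#' Read-length and base-quality statistics of a FASTQ file
#'
#' Computes the read-length histogram and the per-cycle mean base quality,
#' the upload-time QC a sequencing pipeline reports for each sample.
#'
#' @param path FASTQ file.
#' @param offset Quality encoding offset; 33 (Sanger/Illumina 1.8+,
#'   default) or 64 (legacy Illumina).
#' @return A list of class `read_stats`: `total_reads`, `length_histogram`
#'   (named integer vector, names are read lengths), `cycle_mean_quality`
#'   (numeric vector of length `max(read length)`, Phred scale).
#' @export
read_stats <- function(path, offset = 33L) {
  reads <- read_fastq(path)
  n <- nrow(reads)
  if (n == 0L)
    return(structure(list(total_reads = 0L,
                          length_histogram = integer(),
                          cycle_mean_quality = numeric()),
                     class = "read_stats"))
  lens <- nchar(reads$seq)
  hist <- table(lens)
  len_hist <- as.integer(hist)
  names(len_hist) <- names(hist)
  maxlen <- max(lens)
  qsum <- numeric(maxlen)
  qn <- integer(maxlen)
  for (i in seq_len(n)) {
    q <- utf8ToInt(reads$qual[i]) - offset
    k <- length(q)
    qsum[seq_len(k)] <- qsum[seq_len(k)] + q
    qn[seq_len(k)] <- qn[seq_len(k)] + 1L
  }
  structure(
    list(total_reads = n, length_histogram = len_hist,
         cycle_mean_quality = qsum / qn),
    class = "read_stats"
  )
}

#' @export
print.read_stats <- function(x, ...) {
  cat(sprintf("read_stats: %d reads, lengths %s, mean Q %.1f\n",
              x$total_reads,
              paste(names(x$length_histogram), collapse = ","),
              mean(x$cycle_mean_quality)))
  invisible(x)
}
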