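# Minimal text-SAM reader/writer. The toolkit's fixtures and simulator
# output are plain-text SAM; BAM users can pipe through
# `samtools view -h` or Rsamtools::asSam first.

#' Read a plain-text SAM file
#'
#' Parses the eleven mandatory columns; optional tags are ignored.
#'
#' @param path SAM file.
#' @return A `data.frame` with columns `qname`, `flag`, `rname`, `pos`,
#'   `mapq`, `cigar`, `seq`, `qual`, plus derived logicals `unmapped`,
#'   `reverse`, `secondary` (secondary or supplementary) from the FLAG
#'   field. Header `@` lines are available in attribute `"header"`.
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  is_header <- startsWith(lines, "@")
  header <- lines[is_header]
  body <- lines[!is_header]
  if (length(body) == 0L) {
    out <- data.frame(qname = character(), flag = integer(),
                      rname = character(), pos = integer(),
                      mapq = integer(), cigar = character(),
                      seq = character(), qual = character(),
                      unmapped = logical(), reverse = logical(),
                      secondary = logical(), stringsAsFactors = FALSE)
    attr(out, "header") <- header
    return(out)
  }
  fields <- data.table::tstrsplit(body, "\t", fixed = TRUE, keep = 1:11)
  flag <- as.integer(fields[[2]])
  out <- data.frame(
    qname = fields[[1]], flag = flag, rname = fields[[3]],
    pos = as.integer(fields[[4]]), mapq = as.integer(fields[[5]]),
    cigar = fields[[6]], seq = fields[[10]], qual = fields[[11]],
    unmapped = bitwAnd(flag, 4L) > 0L,
    reverse = bitwAnd(flag, 16L) > 0L,
    secondary = bitwAnd(flag, 256L) > 0L | bitwAnd(flag, 2048L) > 0L,
    stringsAsFactors = FALSE
  )
  attr(out, "header") <- header
  out
}

#' Write a plain-text SAM file
#'
#' @param aln data.frame with columns `qname`, `flag`, `rname`, `pos`,
#'   `mapq`, `cigar`, `seq`, `qual`.
#' @param path Output path.
#' @param seqlengths Optional named vector of reference lengths; when
#'   given, `@HD`/`@SQ` header lines are emitted.
#' @return `path`, invisibly.
#' @export
write_sam <- function(aln, path, seqlengths = NULL) {
  header <- character()
  if (!is.null(seqlengths)) {
    header <- c("@HD\tVN:1.6\tSO:coordinate",
                sprintf("@SQ\tSN:%s\tLN:%d", names(seqlengths),
                        as.integer(seqlengths)))
  }
  body <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s",
                  aln$qname, aln$flag, aln$rname, aln$pos, aln$mapq,
                  aln$cigar, aln$seq, aln$qual)
  writeLines(c(header, body), path)
  invisible(path)
}

# Parse CIGAR strings into op/length lists.
.parse_cigar <- function(cigar) {
  lens <- regmatches(cigar, gregexpr("[0-9]+", cigar))
  ops <- regmatches(cigar, gregexpr("[MIDNSHP=X]", cigar))
  Map(function(l, o) list(len = as.integer(l), op = o), lens, ops)
}

# Reference span consumed by each CIGAR (M/=/X/D/N ops).
cigar_ref_width <- function(cigar) {
  parsed <- .parse_cigar(cigar)
  vapply(parsed, function(p)
    sum(p$len[p$op %in% c("M", "=", "X", "D", "N")]), numeric(1))
}

# For one alignment, the (read position, reference position) pairs of
# aligned bases (M/=/X). `pos` is the 1-based leftmost reference position.
.aligned_pairs <- function(cigar, pos) {
  p <- .parse_cigar(cigar)[[1]]
  read_i <- integer(0)
  ref_i <- integer(0)
  r <- 1L
  g <- pos
  for (k in seq_along(p$op)) {
    len <- p$len[k]
    op <- p$op[k]
    if (op %in% c("M", "=", "X")) {
      read_i <- c(read_i, r:(r + len - 1L))
      ref_i <- c(ref_i, g:(g + len - 1L))
      r <- r + len
      g <- g + len
    } else if (op %in% c("I", "S")) {
      r <- r + len
    } else if (op %in% c("D", "N")) {
      g <- g + len
    }
  }
  cbind(read = read_i, ref = ref_i)
}

# Mapped primary alignments as a GRanges (1-based closed intervals).
.sam_granges <- function(aln) {
  use <- !aln$unmapped & !aln$secondary
  aln <- aln[use, , drop = FALSE]
  GenomicRanges::GRanges(
    seqnames = aln$rname,
    ranges = IRanges::IRanges(start = aln$pos,
                              width = cigar_ref_width(aln$cigar)),
    strand = ifelse(aln$reverse, "-", "+"),
    qname = aln$qname
  )
}
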