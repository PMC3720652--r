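#' RPKM of an annotation
#'
#' Reads per kilobase of annotation per million, with a +1 pseudocount on
#' the count so that `log2(rpkm)` is always finite:
#'
#' \deqn{r = \frac{c + 1}{(L / 1000)\,(N / 10^6)}}
#'
#' where `c` is the number of read fragments overlapping the annotation,
#' `L` the annotation length in bases, and `N` a normalization factor —
#' the total aligned fragments of the sample (classic RPKM) or the upper
#' quartile of annotation counts (see [normalization_factor()]).
#'
#' @param c Fragment count(s), non-negative.
#' @param L Annotation length(s) in bases, positive.
#' @param N Normalization factor(s), positive.
#' @return RPKM value(s), strictly positive.
#' @examples
#' rpkm(0, 1000, 1e6)   # 1
#' rpkm(9, 500, 2e6)    # 10
#' @export
rpkm <- function(c, L, N) {
  if (any(L <= 0)) stop("annotation length L must be positive")
  if (any(N <= 0)) stop("normalization factor N must be positive")
  if (any(c < 0)) stop("counts must be non-negative")
  (c + 1) / (L / 1000) / (N / 1e6)
}

#' Per-sample normalization factors
#'
#' `"total"` uses the total number of aligned read fragments in the
#' sample. `"upper-quartile"` instead uses the 75th percentile
#' (nearest-rank) of the sample's annotation counts, restricted to
#' annotations with nonzero count, which reduces the dominance of a few
#' highly expressed genes on the scaling.
#'
#' @param count_table A [count_fragments()] result.
#' @param method `"total"` or `"upper-quartile"`.
#' @return Named numeric vector of factors, one per sample.
#' @export
normalization_factor <- function(count_table,
                                 method = c("total", "upper-quartile")) {
  method <- match.arg(method)
  if (method == "total") {
    N <- as.numeric(count_table$totals)
    names(N) <- count_table$samples
    return(N)
  }
  N <- vapply(count_table$samples, function(s) {
    cnt <- count_table$counts[, s]
    cnt <- cnt[cnt > 0]
    if (length(cnt) == 0L)
      stop("sample ", s, " has no nonzero annotation counts; ",
           "upper-quartile factor undefined")
    sorted <- sort(cnt)
    sorted[ceiling(0.75 * length(sorted))]
  }, numeric(1))
  N
}

#' Heptamer priming-bias read weights
#'
#' Random-hexamer priming biases the base composition of read starts.
#' Each read is weighted by the ratio of its initial heptamer's frequency
#' in a distal positional window (where priming bias has decayed) to its
#' frequency at read starts:
#' `w(read) = f_distal(h) / f_start(h)` with `h` the heptamer at read
#' positions 1-7. Over-represented start heptamers are down-weighted
#' below 1, and weighted fragment counts `sum w` replace raw counts in
#' normalization. Heptamers never seen in the distal window get weight 0.
#'
#' @param reads FASTQ path or [read_fastq()] data.frame.
#' @param distal_start,distal_end 1-based read positions of the distal
#'   window in which background heptamer frequencies are estimated
#'   (default positions 24-30, i.e. heptamers starting there).
#' @return Named numeric vector: read id -> weight. Reads too short for
#'   the distal window get weight 1 with a warning.
#' @export
heptamer_weights <- function(reads, distal_start = 24L, distal_end = 30L) {
  if (is.character(reads)) reads <- read_fastq(reads)
  k <- 7L
  need <- distal_end + k - 1L
  n <- nrow(reads)
  w <- stats::setNames(rep(1, n), reads$id)
  long <- nchar(reads$seq) >= need
  if (any(!long))
    warning(sum(!long), " read(s) shorter than ", need,
            " bases; weight 1 assigned")
  if (!any(long)) return(w)
  seqs <- reads$seq[long]
  start_hept <- substr(seqs, 1L, k)
  distal <- unlist(lapply(distal_start:distal_end, function(p)
    substr(seqs, p, p + k - 1L)), use.names = FALSE)
  f_start <- table(start_hept) / length(start_hept)
  f_distal <- table(distal) / length(distal)
  fd <- as.numeric(f_distal[start_hept])
  fd[is.na(fd)] <- 0
  fs <- as.numeric(f_start[start_hept])
  w[which(long)] <- fd / fs
  w
}
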