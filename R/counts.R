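#' Count aligned fragments over annotations
#'
#' One mapped primary alignment record is one fragment; secondary and
#' supplementary records are ignored. A fragment is counted for every
#' annotation it overlaps by at least one base (strand-blind by default),
#' so a fragment spanning two overlapping annotations contributes to both.
#' With read weights the contribution of a fragment is its weight instead
#' of 1; the raw integer counts are kept alongside because exact tests
#' require them.
#'
#' @param alignments Named list: one SAM path or [read_sam()] data.frame
#'   per sample. Alignments must be coordinate-sorted.
#' @param annotations `GRanges` with metadata column `id` (see
#'   [read_annotations()] / [make_annotations()]).
#' @param weights Optional named list (per sample) of read-id -> weight
#'   vectors, e.g. from [heptamer_weights()]; unit weights reproduce
#'   unweighted counting exactly.
#' @param stranded If `TRUE`, only fragments on the annotation's strand
#'   are counted.
#' @return A `count_table` object: list with `counts` (weighted
#'   annotation x sample matrix), `raw_counts` (integer matrix),
#'   `totals` (per-sample mapped primary fragments), `annotation_id`,
#'   `samples`.
#' @export
count_fragments <- function(alignments, annotations, weights = NULL,
                            stranded = FALSE) {
  stopifnot(!is.null(names(alignments)), all(nzchar(names(alignments))))
  samples <- names(alignments)
  ids <- annotations$id
  n_ann <- length(annotations)
  counts <- matrix(0, nrow = n_ann, ncol = length(samples),
                   dimnames = list(ids, samples))
  raw <- matrix(0L, nrow = n_ann, ncol = length(samples),
                dimnames = list(ids, samples))
  totals <- stats::setNames(integer(length(samples)), samples)

  for (s in samples) {
    aln <- alignments[[s]]
    if (is.character(aln)) aln <- read_sam(aln)
    aln <- aln[!aln$unmapped & !aln$secondary, , drop = FALSE]
    .check_sorted(aln, s)
    totals[s] <- nrow(aln)
    if (nrow(aln) == 0L) next
    frag <- .sam_granges(aln)
    missing_chrom <- setdiff(
      as.character(unique(GenomicRanges::seqnames(annotations))),
      as.character(unique(GenomicRanges::seqnames(frag))))
    if (length(missing_chrom) && totals[s] > 0L)
      warning("sample ", s, ": no alignments on annotation chromosome(s) ",
              paste(missing_chrom, collapse = ", "),
              "; counts there are zero")
    hits <- GenomicRanges::findOverlaps(
      annotations, frag,
      ignore.strand = !stranded, minoverlap = 1L)
    if (length(hits) == 0L) next
    ann_i <- S4Vectors::queryHits(hits)
    frag_i <- S4Vectors::subjectHits(hits)
    w <- rep(1, length(frag_i))
    if (!is.null(weights) && !is.null(weights[[s]])) {
      wv <- weights[[s]]
      found <- frag$qname[frag_i] %in% names(wv)
      w[found] <- unname(wv[frag$qname[frag_i][found]])
    }
    tab <- rowsum(w, group = ann_i)
    raw_tab <- rowsum(rep(1L, length(frag_i)), group = ann_i)
    at <- as.integer(rownames(tab))
    counts[at, s] <- tab[, 1]
    raw[at, s] <- as.integer(raw_tab[, 1])
  }
  structure(
    list(counts = counts, raw_counts = raw, totals = totals,
         annotation_id = ids, samples = samples),
    class = "count_table"
  )
}

.check_sorted <- function(aln, sample) {
  if (nrow(aln) < 2L) return(invisible(TRUE))
  ok <- all(tapply(aln$pos, aln$rname, function(p) !is.unsorted(p)))
  if (!ok)
    stop("alignments for sample ", sample,
         " are not coordinate-sorted; sort them first ",
         "(e.g. samtools sort)")
  invisible(TRUE)
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("count_table: %d annotations x %d samples; totals: %s\n",
              nrow(x$counts), ncol(x$counts),
              paste(x$totals, collapse = ", ")))
  invisible(x)
}

#' Count reads spanning splice junctions
#'
#' Each `N` (skipped-region) operation of a gapped alignment implies one
#' exon-exon junction, keyed by chromosome and the 1-based first/last
#' intronic positions (donor/acceptor side). A read spanning k junctions
#' increments k junction counts; ungapped reads contribute nothing.
#'
#' @param alignments SAM path or [read_sam()] data.frame.
#' @return data.frame with columns `chrom`, `donor`, `acceptor`, `count`,
#'   sorted by coordinate.
#' @export
count_junction_reads <- function(alignments) {
  aln <- if (is.character(alignments)) read_sam(alignments) else alignments
  aln <- aln[!aln$unmapped & !aln$secondary, , drop = FALSE]
  gapped <- grepl("N", aln$cigar, fixed = TRUE)
  empty <- data.frame(chrom = character(), donor = integer(),
                      acceptor = integer(), count = integer(),
                      stringsAsFactors = FALSE)
  if (!any(gapped)) return(empty)
  aln <- aln[gapped, , drop = FALSE]
  keys <- character()
  for (i in seq_len(nrow(aln))) {
    p <- .parse_cigar(aln$cigar[i])[[1]]
    g <- aln$pos[i]
    for (k in seq_along(p$op)) {
      if (p$op[k] %in% c("M", "=", "X", "D")) {
        g <- g + p$len[k]
      } else if (p$op[k] == "N") {
        keys <- c(keys, sprintf("%s\t%d\t%d", aln$rname[i], g,
                                g + p$len[k] - 1L))
        g <- g + p$len[k]
      }
    }
  }
  tab <- table(keys)
  parts <- data.table::tstrsplit(names(tab), "\t", fixed = TRUE)
  out <- data.frame(chrom = parts[[1]], donor = as.integer(parts[[2]]),
                    acceptor = as.integer(parts[[3]]),
                    count = as.integer(tab), stringsAsFactors = FALSE)
  out[order(out$chrom, out$donor, out$acceptor), , drop = FALSE]
}
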