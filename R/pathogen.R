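# Contamination/pathogen screening: reads that fail to map to the study
# organism's reference are candidate foreign material. They are
# extracted, optionally adapter-trimmed, assembled into contigs
# (assembly itself is out of scope; match records are consumed), and
# contig hits against a reference database are filtered before any
# organism is reported.

#' Extract unmapped reads
#'
#' Returns, in input order, the reads of the FASTQ file that have no
#' mapped alignment record.
#'
#' @param alignments SAM path or [read_sam()] data.frame.
#' @param reads FASTQ path or [read_fastq()] data.frame.
#' @return data.frame of unmapped reads (`id`, `seq`, `qual`).
#' @export
extract_unmapped <- function(alignments, reads) {
  aln <- if (is.character(alignments)) read_sam(alignments) else alignments
  rds <- if (is.character(reads)) read_fastq(reads) else reads
  aln_ids <- unique(aln$qname)
  unknown <- setdiff(aln_ids, rds$id)
  if (length(unknown))
    stop("alignment read id not present in reads file: ", unknown[1])
  mapped <- unique(aln$qname[!aln$unmapped])
  rds[!(rds$id %in% mapped), , drop = FALSE]
}

#' Trim a 3' adapter, only when the match exceeds four bases
#'
#' The longest suffix of the read exactly matching a prefix of the
#' adapter is removed if and only if the matched length exceeds 4 bp;
#' shorter terminal matches are too likely by chance and the read is
#' left unchanged. Quality strings are trimmed in lockstep.
#'
#' @param seq Read sequence(s).
#' @param adapter Adapter sequence (non-empty).
#' @param qual Optional quality string(s), same lengths as `seq`.
#' @param min_overlap Matches of this length or shorter are ignored
#'   (default 4).
#' @return If `qual` is `NULL`, the trimmed sequence(s); otherwise a
#'   data.frame with columns `seq` and `qual`.
#' @export
trim_adapter <- function(seq, adapter, qual = NULL, min_overlap = 4L) {
  if (!nzchar(adapter)) stop("adapter must be non-empty")
  match_len <- vapply(seq, function(s) {
    n <- nchar(s)
    best <- 0L
    upper <- min(n, nchar(adapter))
    for (k in seq_len(upper)) {
      if (substr(s, n - k + 1L, n) == substr(adapter, 1L, k))
        best <- k
    }
    best
  }, integer(1), USE.NAMES = FALSE)
  cut <- ifelse(match_len > min_overlap, match_len, 0L)
  trimmed <- substr(seq, 1L, nchar(seq) - cut)
  if (is.null(qual)) return(trimmed)
  stopifnot(all(nchar(qual) == nchar(seq)))
  data.frame(seq = trimmed, qual = substr(qual, 1L, nchar(qual) - cut),
             stringsAsFactors = FALSE)
}

#' Read a 12-column tabular contig match file
#'
#' Standard tabular search output: query, subject, identity, alignment
#' length, mismatches, gap opens, qstart, qend, sstart, send, evalue,
#' bitscore. A `sample` column may precede the 12 (13-column variant)
#' to carry multi-sample tables; otherwise `sample` defaults to the
#' file name.
#'
#' @param path Tab-delimited match file.
#' @param organism_map Optional named character vector mapping subject
#'   ids to organism names; default uses the subject id itself.
#' @return data.frame with columns `sample`, `contig`, `subject`,
#'   `organism`, `alignment_length`, `evalue`.
#' @export
read_contig_matches <- function(path, organism_map = NULL) {
  d <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(d) == 13L) {
    sample <- d[[1]]
    d <- d[, -1, drop = FALSE]
  } else if (ncol(d) == 12L) {
    sample <- rep(basename(path), nrow(d))
  } else {
    stop("expected 12 or 13 tab-delimited columns, got ", ncol(d))
  }
  alen <- suppressWarnings(as.numeric(d[[4]]))
  eval <- suppressWarnings(as.numeric(d[[11]]))
  bad <- which(is.na(alen) | is.na(eval) | alen < 0 | eval < 0)
  if (length(bad))
    stop("missing or negative alignment length/E-value at line ", bad[1])
  subject <- as.character(d[[2]])
  organism <- if (is.null(organism_map)) subject else {
    out <- unname(organism_map[subject])
    ifelse(is.na(out), subject, out)
  }
  data.frame(sample = as.character(sample), contig = as.character(d[[1]]),
             subject = subject, organism = organism,
             alignment_length = alen, evalue = eval,
             stringsAsFactors = FALSE)
}

#' Filter contig matches to annotated hits
#'
#' A contig match is annotated only if it aligns over more than
#' `min_match_bp` bases AND its E-value is below `max_evalue`; both
#' thresholds are strict. The filter is idempotent and order-preserving.
#'
#' @param matches data.frame with columns `alignment_length` and
#'   `evalue` (see [read_contig_matches()]).
#' @param min_match_bp Alignment-length threshold, default 150 (a match
#'   must exceed it).
#' @param max_evalue E-value threshold, default `1e-6` (a match must be
#'   strictly below it).
#' @return The annotated subset, same columns, original order.
#' @export
annotate_contigs <- function(matches, min_match_bp = 150,
                             max_evalue = 1e-6) {
  stopifnot(all(c("alignment_length", "evalue") %in% names(matches)))
  keep <- matches$alignment_length > min_match_bp &
    matches$evalue < max_evalue
  matches[keep, , drop = FALSE]
}

#' Per-organism sample summary of annotated matches
#'
#' For each organism, `N` is the number of distinct samples with at
#' least one annotated contig for that organism — duplicated hits within
#' a sample do not inflate it. Per-sample contig counts are retained so
#' low-complexity signals (a handful of contigs in a few samples) can be
#' distinguished from pervasive ones.
#'
#' @param annotated Annotated matches (see [annotate_contigs()]).
#' @param samples Character vector of all screened sample ids (bounds
#'   `N` and catches typos).
#' @return List with `summary` (data.frame `organism`, `N`, sorted by
#'   `N` descending then organism) and `per_sample` (data.frame
#'   `organism`, `sample`, `contigs`).
#' @export
species_summary <- function(annotated, samples) {
  unknown <- setdiff(unique(annotated$sample), samples)
  if (length(unknown))
    stop("match sample(s) absent from sample list: ",
         paste(unknown, collapse = ", "))
  if (nrow(annotated) == 0L)
    return(list(
      summary = data.frame(organism = character(), N = integer(),
                           stringsAsFactors = FALSE),
      per_sample = data.frame(organism = character(), sample = character(),
                              contigs = integer(), stringsAsFactors = FALSE)))
  per <- stats::aggregate(
    list(contigs = annotated$contig),
    by = list(organism = annotated$organism, sample = annotated$sample),
    FUN = function(x) length(unique(x)))
  smry <- stats::aggregate(list(N = per$sample),
                           by = list(organism = per$organism),
                           FUN = function(x) length(unique(x)))
  smry <- smry[order(-smry$N, smry$organism), , drop = FALSE]
  rownames(smry) <- NULL
  list(summary = smry,
       per_sample = per[order(per$organism, per$sample), , drop = FALSE])
}

#' Passthrough assembler stub
#'
#' Treats every unmapped read as its own contig, enabling end-to-end
#' desk tests of the screening pipeline without a real assembler
#' (assembly is delegated to external tools in production).
#'
#' @param reads data.frame of reads (`id`, `seq`).
#' @return data.frame with `contig` ids and `seq`.
#' @export
passthrough_assembler <- function(reads) {
  data.frame(contig = paste0("contig_", seq_len(nrow(reads))),
             seq = reads$seq, stringsAsFactors = FALSE)
}
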