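#' Read annotation intervals from BED or GTF
#'
#' BED intervals are 0-based half-open on disk, GTF 1-based inclusive;
#' both are converted to the 1-based closed convention used throughout the
#' package (GRanges). Element ids come from the BED name column or the
#' GTF `gene_id` attribute, falling back to `chrom:start-end`.
#'
#' @param path BED or GTF file; format inferred from the extension unless
#'   given.
#' @param format `"bed"`, `"gtf"`, or `"auto"`.
#' @return A `GRanges` with metadata column `id`.
#' @export
read_annotations <- function(path, format = c("auto", "bed", "gtf")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
    format <- switch(ext, bed = "bed", gtf = "gtf", gff = "gtf",
                     stop("cannot infer annotation format from: ", path))
  }
  gr <- rtracklayer::import(path, format = format)
  id <- if (format == "bed" && !is.null(gr$name)) {
    as.character(gr$name)
  } else if (format == "gtf" && !is.null(gr$gene_id)) {
    as.character(gr$gene_id)
  } else {
    sprintf("%s:%d-%d", as.character(GenomicRanges::seqnames(gr)),
            GenomicRanges::start(gr), GenomicRanges::end(gr))
  }
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(id = id)
  gr
}

#' Build annotations from a data.frame
#'
#' @param df data.frame with columns `id`, `chrom`, `start`, `end`
#'   (1-based closed) and optionally `strand`.
#' @return A `GRanges` with metadata column `id`.
#' @export
make_annotations <- function(df) {
  stopifnot(all(c("id", "chrom", "start", "end") %in% names(df)))
  if (any(df$end < df$start)) stop("annotation with end < start")
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start, end = df$end),
    strand = if ("strand" %in% names(df)) df$strand else "*",
    id = as.character(df$id)
  )
}

#' Write annotations to BED
#'
#' Converts back from the internal 1-based closed intervals to BED's
#' 0-based half-open coordinates.
#'
#' @param gr `GRanges` with metadata column `id`.
#' @param path Output BED path.
#' @return `path`, invisibly.
#' @export
write_annotations_bed <- function(gr, path) {
  out <- gr
  names(S4Vectors::mcols(out))[names(S4Vectors::mcols(out)) == "id"] <- "name"
  rtracklayer::export(out, path, format = "bed")
  invisible(path)
}
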