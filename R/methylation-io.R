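# VCF 4.1 encoding of base-level methylation. One record per cytosine
# site; per-sample rate and counts travel in genotype fields, per-
# comparison differential-methylation statistics in INFO.

.VCF_FORMAT_FIELDS <- c(
  '##FORMAT=<ID=MR,Number=1,Type=Float,Description="Methylation rate Cm/(Cm+Cu)">',
  '##FORMAT=<ID=MC,Number=1,Type=Integer,Description="Unconverted cytosine count (methylated evidence)">',
  '##FORMAT=<ID=UC,Number=1,Type=Integer,Description="Converted cytosine count (unmethylated evidence)">'
)

#' Write methylation sites to VCF 4.1
#'
#' One record per site: REF is the reference base of the cytosine (`C`
#' on the plus strand, `G` on the minus strand), per-sample
#' rate/counts go to the genotype fields `MR:MC:UC`, strand and context
#' to INFO `STR`/`CX`, and — when a differential-methylation result is
#' supplied — per-comparison p/q values to INFO fields
#' `FP_<comparison>` / `FQ_<comparison>`. Input must already be sorted
#' by `(chrom, pos)`; the writer refuses to reorder silently.
#'
#' @param sites A [call_methylation_sites()] table, optionally with
#'   [diff_methylation()] columns.
#' @param path Output VCF path.
#' @return `path`, invisibly.
#' @export
write_methylation_vcf <- function(sites, path) {
  samples <- attr(sites, "samples")
  comparisons <- attr(sites, "comparisons")
  if (nrow(sites) > 1L) {
    o <- order(sites$chrom, sites$pos)
    if (!identical(o, seq_len(nrow(sites))))
      stop("sites must be sorted by (chrom, pos) before writing VCF")
  }
  info_hdr <- c(
    '##INFO=<ID=STR,Number=1,Type=String,Description="Strand of the cytosine">',
    '##INFO=<ID=CX,Number=1,Type=String,Description="Cytosine context (CpG/CHG/CHH/unknown)">'
  )
  for (cmp in comparisons) {
    info_hdr <- c(info_hdr,
      sprintf('##INFO=<ID=FP_%s,Number=1,Type=Float,Description="Fisher exact p, comparison %s">', cmp, cmp),
      sprintf('##INFO=<ID=FQ_%s,Number=1,Type=Float,Description="BH-adjusted Fisher p, comparison %s">', cmp, cmp))
  }
  header <- c(
    "##fileformat=VCFv4.1",
    "##source=gobylite methylation",
    info_hdr,
    .VCF_FORMAT_FIELDS,
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", samples), collapse = "\t")
  )
  fmt_num <- function(x) ifelse(is.na(x), ".", sprintf("%.6g", x))
  body <- character(nrow(sites))
  if (nrow(sites)) {
    info <- sprintf("STR=%s;CX=%s", sites$strand, sites$context)
    for (cmp in comparisons) {
      p <- sites[[paste0("fisher_p.", cmp)]]
      q <- sites[[paste0("fisher_q.", cmp)]]
      info <- paste0(info, ";FP_", cmp, "=", fmt_num(p),
                     ";FQ_", cmp, "=", fmt_num(q))
    }
    geno <- rep("", nrow(sites))
    for (s in samples) {
      g <- sprintf("%s:%d:%d",
                   fmt_num(sites[[paste0("rate.", s)]]),
                   sites[[paste0("Cm.", s)]], sites[[paste0("Cu.", s)]])
      geno <- paste0(geno, "\t", g)
    }
    body <- sprintf("%s\t%d\t.\t%s\t.\t.\t.\t%s\tMR:MC:UC%s",
                    sites$chrom, sites$pos,
                    ifelse(sites$strand == "+", "C", "G"), info, geno)
  }
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a methylation VCF back into a site table
#'
#' Inverse of [write_methylation_vcf()]; rates are recomputed from the
#' MC/UC counts so the round trip is exact.
#'
#' @param path VCF path.
#' @return A `methylation_sites` data.frame.
#' @export
read_methylation_vcf <- function(path) {
  lines <- readLines(path)
  chrom_line <- grep("^#CHROM", lines, value = TRUE)
  if (length(chrom_line) != 1L) stop("missing #CHROM header line")
  cols <- strsplit(chrom_line, "\t", fixed = TRUE)[[1]]
  samples <- if (length(cols) > 9L) cols[10:length(cols)] else character()
  body <- lines[!startsWith(lines, "#")]
  body <- body[nzchar(body)]
  out <- data.frame(chrom = character(), pos = integer(),
                    strand = character(), context = character(),
                    stringsAsFactors = FALSE)
  if (length(body)) {
    f <- data.table::tstrsplit(body, "\t", fixed = TRUE)
    info <- f[[8]]
    get_info <- function(key) {
      m <- regmatches(info, regexpr(paste0("(^|;)", key, "=[^;]*"), info))
      sub(paste0("^;?", key, "="), "", m)
    }
    out <- data.frame(
      chrom = f[[1]], pos = as.integer(f[[2]]),
      strand = get_info("STR"), context = get_info("CX"),
      stringsAsFactors = FALSE
    )
    for (j in seq_along(samples)) {
      parts <- data.table::tstrsplit(f[[9L + j]], ":", fixed = TRUE)
      Cm <- as.integer(parts[[2]])
      Cu <- as.integer(parts[[3]])
      out[[paste0("Cm.", samples[j])]] <- Cm
      out[[paste0("Cu.", samples[j])]] <- Cu
      out[[paste0("rate.", samples[j])]] <- methylation_rate(Cm, Cu)
    }
  } else {
    for (s in samples) {
      out[[paste0("Cm.", s)]] <- integer()
      out[[paste0("Cu.", s)]] <- integer()
      out[[paste0("rate.", s)]] <- numeric()
    }
  }
  attr(out, "samples") <- samples
  class(out) <- c("methylation_sites", "data.frame")
  out
}

#' Write region methylation as an IGV track
#'
#' Tab-delimited `.igv` track dialect: `Chromosome`, `Start` (0-based),
#' `End`, `Feature`, then one numeric column per sample holding the
#' region methylation rate.
#'
#' @param regions An [aggregate_regions()] table, sorted by coordinate.
#' @param path Output `.igv` path.
#' @return `path`, invisibly.
#' @export
write_region_igv <- function(regions, path) {
  samples <- attr(regions, "samples")
  fmt_num <- function(x) ifelse(is.na(x), "NA", sprintf("%.6g", x))
  header <- paste(c("Chromosome", "Start", "End", "Feature", samples),
                  collapse = "\t")
  lines <- header
  if (nrow(regions)) {
    vals <- sapply(samples, function(s)
      fmt_num(regions[[paste0("rate.", s)]]))
    if (is.null(dim(vals)))
      vals <- matrix(vals, nrow = nrow(regions))
    body <- paste(regions$chrom, regions$start - 1L, regions$end,
                  regions$id, apply(vals, 1L, paste, collapse = "\t"),
                  sep = "\t")
    lines <- c(lines, body)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read an IGV region track back
#'
#' @param path `.igv` path written by [write_region_igv()].
#' @return data.frame with `id`, `chrom`, `start`, `end` (1-based
#'   closed) and `rate.<sample>` columns.
#' @export
read_region_igv <- function(path) {
  d <- utils::read.delim(path, check.names = FALSE)
  samples <- setdiff(names(d), c("Chromosome", "Start", "End", "Feature"))
  out <- data.frame(id = as.character(d$Feature),
                    chrom = as.character(d$Chromosome),
                    start = d$Start + 1L, end = d$End,
                    stringsAsFactors = FALSE)
  for (s in samples) out[[paste0("rate.", s)]] <- as.numeric(d[[s]])
  attr(out, "samples") <- samples
  out
}
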