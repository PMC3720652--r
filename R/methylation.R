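# Bisulfite methylation calling. Bisulfite treatment converts
# unmethylated cytosine to uracil (sequenced as T) and leaves methylated
# cytosine intact, so at every reference cytosine the C:T ratio of
# covering reads estimates the methylation rate. Cytosines live on both
# strands: a + strand cytosine is a reference C interrogated by
# forward-aligned reads (C = methylated evidence, T = unmethylated); a
# - strand cytosine appears as a reference G and is interrogated by
# reverse-aligned reads (G = methylated, A = unmethylated, the
# complements seen in reference-forward orientation). Any other base at
# the site is non-informative and ignored.

# Genome as a per-chromosome list of single-character vectors.
.genome_chars <- function(genome) {
  if (is.character(genome) && length(genome) == 1L && file.exists(genome))
    genome <- Biostrings::readDNAStringSet(genome)
  if (inherits(genome, "DNAStringSet")) {
    chars <- lapply(as.character(genome), function(s)
      strsplit(s, "", fixed = TRUE)[[1]])
    names(chars) <- sub("\\s.*$", "", names(genome))
    return(chars)
  }
  if (is.list(genome)) return(genome)
  stop("genome must be a FASTA path or DNAStringSet")
}

# Per-base (chrom, ref position, read base, read strand) tuples of all
# mapped primary alignments. Fast path for pure-match CIGARs.
.pileup_bases <- function(aln) {
  aln <- aln[!aln$unmapped & !aln$secondary, , drop = FALSE]
  if (nrow(aln) == 0L)
    return(data.frame(rname = character(), refpos = integer(),
                      base = character(), reverse = logical()))
  simple <- grepl("^[0-9]+M$", aln$cigar)
  pieces <- list()
  if (any(simple)) {
    sub <- aln[simple, , drop = FALSE]
    lens <- nchar(sub$seq)
    refpos <- rep(sub$pos, lens) + sequence(lens) - 1L
    pieces[[1]] <- data.frame(
      rname = rep(sub$rname, lens),
      refpos = refpos,
      base = unlist(strsplit(sub$seq, "", fixed = TRUE),
                    use.names = FALSE),
      reverse = rep(sub$reverse, lens),
      stringsAsFactors = FALSE
    )
  }
  if (any(!simple)) {
    sub <- aln[!simple, , drop = FALSE]
    rows <- lapply(seq_len(nrow(sub)), function(i) {
      ap <- .aligned_pairs(sub$cigar[i], sub$pos[i])
      bases <- strsplit(sub$seq[i], "", fixed = TRUE)[[1]]
      data.frame(rname = sub$rname[i], refpos = ap[, "ref"],
                 base = bases[ap[, "read"]], reverse = sub$reverse[i],
                 stringsAsFactors = FALSE)
    })
    pieces[[length(pieces) + 1L]] <- do.call(rbind, rows)
  }
  do.call(rbind, pieces)
}

#' Call per-cytosine methylation sites from bisulfite alignments
#'
#' For every reference cytosine (both strands) covered by at least one
#' informative base, tallies per sample the unconverted count `Cm`
#' (methylated evidence), the converted count `Cu` (unmethylated
#' evidence), and the methylation rate `Cm / (Cm + Cu)`. Sites with no
#' informative observation in any sample are not emitted.
#'
#' @param alignments Named list: one SAM path or [read_sam()] data.frame
#'   of bisulfite alignments per sample.
#' @param genome Reference FASTA path or `DNAStringSet` the reads were
#'   aligned to.
#' @return A data.frame of class `methylation_sites`, sorted by
#'   `(chrom, pos)`: columns `chrom`, `pos` (1-based), `strand`,
#'   `context` (`CpG`/`CHG`/`CHH`/`unknown`, assigned from the reference
#'   and reported but never filtered on), and per sample `Cm.<s>`,
#'   `Cu.<s>`, `rate.<s>`. Attribute `"samples"` holds the sample names.
#' @export
call_methylation_sites <- function(alignments, genome) {
  stopifnot(!is.null(names(alignments)), all(nzchar(names(alignments))))
  chars <- .genome_chars(genome)
  samples <- names(alignments)
  per_sample <- list()
  for (s in samples) {
    aln <- alignments[[s]]
    if (is.character(aln)) aln <- read_sam(aln)
    bad <- setdiff(unique(aln$rname[!aln$unmapped]), names(chars))
    if (length(bad))
      stop("alignment sequence(s) absent from genome: ",
           paste(bad, collapse = ", "))
    pb <- .pileup_bases(aln)
    if (nrow(pb) == 0L) {
      per_sample[[s]] <- data.frame(chrom = character(), pos = integer(),
                                    Cm = integer(), Cu = integer())
      next
    }
    ref <- unlist(lapply(split(seq_len(nrow(pb)), pb$rname), function(i)
      chars[[pb$rname[i[1]]]][pb$refpos[i]]), use.names = FALSE)
    ord <- unlist(split(seq_len(nrow(pb)), pb$rname), use.names = FALSE)
    pb <- pb[ord, , drop = FALSE]
    meth <- (ref == "C" & !pb$reverse & pb$base == "C") |
            (ref == "G" &  pb$reverse & pb$base == "G")
    unmeth <- (ref == "C" & !pb$reverse & pb$base == "T") |
              (ref == "G" &  pb$reverse & pb$base == "A")
    keep <- meth | unmeth
    if (!any(keep)) {
      per_sample[[s]] <- data.frame(chrom = character(), pos = integer(),
                                    Cm = integer(), Cu = integer())
      next
    }
    key <- paste(pb$rname[keep], pb$refpos[keep], sep = "\r")
    cm <- rowsum(as.integer(meth[keep]), key)
    cu <- rowsum(as.integer(unmeth[keep]), key)
    parts <- data.table::tstrsplit(rownames(cm), "\r", fixed = TRUE)
    per_sample[[s]] <- data.frame(chrom = parts[[1]],
                                  pos = as.integer(parts[[2]]),
                                  Cm = as.integer(cm[, 1]),
                                  Cu = as.integer(cu[, 1]),
                                  stringsAsFactors = FALSE)
  }
  all_sites <- unique(do.call(rbind, lapply(per_sample, function(d)
    d[c("chrom", "pos")])))
  if (is.null(all_sites) || nrow(all_sites) == 0L) {
    out <- data.frame(chrom = character(), pos = integer(),
                      strand = character(), context = character())
    for (s in samples) {
      out[[paste0("Cm.", s)]] <- integer()
      out[[paste0("Cu.", s)]] <- integer()
      out[[paste0("rate.", s)]] <- numeric()
    }
    attr(out, "samples") <- samples
    class(out) <- c("methylation_sites", "data.frame")
    return(out)
  }
  all_sites <- all_sites[order(all_sites$chrom, all_sites$pos), ,
                         drop = FALSE]
  rownames(all_sites) <- NULL
  refbase <- mapply(function(ch, p) chars[[ch]][p],
                    all_sites$chrom, all_sites$pos)
  out <- data.frame(
    chrom = all_sites$chrom, pos = all_sites$pos,
    strand = ifelse(refbase == "C", "+", "-"),
    context = .cytosine_context(chars, all_sites$chrom, all_sites$pos,
                                refbase),
    stringsAsFactors = FALSE
  )
  site_key <- paste(out$chrom, out$pos, sep = "\r")
  for (s in samples) {
    d <- per_sample[[s]]
    m <- match(site_key, paste(d$chrom, d$pos, sep = "\r"))
    Cm <- ifelse(is.na(m), 0L, d$Cm[m])
    Cu <- ifelse(is.na(m), 0L, d$Cu[m])
    out[[paste0("Cm.", s)]] <- Cm
    out[[paste0("Cu.", s)]] <- Cu
    out[[paste0("rate.", s)]] <- methylation_rate(Cm, Cu)
  }
  attr(out, "samples") <- samples
  class(out) <- c("methylation_sites", "data.frame")
  out
}

# Trinucleotide context of a cytosine from the reference only.
.cytosine_context <- function(chars, chrom, pos, refbase) {
  vapply(seq_along(pos), function(i) {
    g <- chars[[chrom[i]]]
    p <- pos[i]
    if (refbase[i] == "C") {
      if (p + 1L > length(g)) return("unknown")
      if (g[p + 1L] == "G") return("CpG")
      if (p + 2L > length(g)) return("unknown")
      if (g[p + 2L] == "G") return("CHG")
      return("CHH")
    }
    if (p - 1L < 1L) return("unknown")
    if (g[p - 1L] == "C") return("CpG")
    if (p - 2L < 1L) return("unknown")
    if (g[p - 2L] == "C") return("CHG")
    "CHH"
  }, character(1))
}

#' Methylation rate from converted/unconverted counts
#'
#' `Cm / (Cm + Cu)` with no pseudocount; a site with zero informative
#' coverage gets `NA` (a no-call), never 0.
#'
#' @param Cm Unconverted (methylated) counts.
#' @param Cu Converted (unmethylated) counts.
#' @return Rates in `[0, 1]`, `NA` where `Cm + Cu == 0`.
#' @export
methylation_rate <- function(Cm, Cu) {
  if (any(Cm < 0 | Cu < 0)) stop("counts must be non-negative")
  tot <- Cm + Cu
  ifelse(tot > 0, Cm / tot, NA_real_)
}

#' Aggregate site methylation over annotated regions
#'
#' Per region and sample, counts are summed over member sites and the
#' region rate recomputed from the summed counts (count-weighted, not a
#' mean of site rates). Regions containing no site are emitted with zero
#' counts and a no-call rate.
#'
#' @param sites A [call_methylation_sites()] table.
#' @param annotations `GRanges` with metadata column `id` (e.g. CpG
#'   islands, promoters, gene bodies).
#' @return data.frame of class `region_methylation`: `id`, `chrom`,
#'   `start`, `end`, and per sample `Cm.<s>`, `Cu.<s>`, `rate.<s>`.
#' @export
aggregate_regions <- function(sites, annotations) {
  samples <- attr(sites, "samples")
  site_gr <- GenomicRanges::GRanges(
    seqnames = sites$chrom,
    ranges = IRanges::IRanges(start = sites$pos, width = 1L))
  hits <- GenomicRanges::findOverlaps(annotations, site_gr,
                                      ignore.strand = TRUE)
  out <- data.frame(
    id = annotations$id,
    chrom = as.character(GenomicRanges::seqnames(annotations)),
    start = GenomicRanges::start(annotations),
    end = GenomicRanges::end(annotations),
    stringsAsFactors = FALSE
  )
  q <- S4Vectors::queryHits(hits)
  subj <- S4Vectors::subjectHits(hits)
  for (s in samples) {
    Cm <- integer(nrow(out))
    Cu <- integer(nrow(out))
    if (length(hits)) {
      cm_sum <- rowsum(sites[[paste0("Cm.", s)]][subj], q)
      cu_sum <- rowsum(sites[[paste0("Cu.", s)]][subj], q)
      at <- as.integer(rownames(cm_sum))
      Cm[at] <- as.integer(cm_sum[, 1])
      Cu[at] <- as.integer(cu_sum[, 1])
    }
    out[[paste0("Cm.", s)]] <- Cm
    out[[paste0("Cu.", s)]] <- Cu
    out[[paste0("rate.", s)]] <- methylation_rate(Cm, Cu)
  }
  attr(out, "samples") <- samples
  class(out) <- c("region_methylation", "data.frame")
  out
}

#' Define sample groups and the comparisons between them
#'
#' @param groups Named list: group label -> character vector of sample
#'   names. At most 10 groups; a sample belongs to exactly one group.
#' @param comparisons List of length-2 character vectors of group labels;
#'   any number of pairwise comparisons may be declared.
#' @return A `group_design` object.
#' @export
group_design <- function(groups, comparisons) {
  stopifnot(is.list(groups), !is.null(names(groups)))
  if (length(groups) > 10L)
    stop("at most 10 groups are supported")
  all_samples <- unlist(groups, use.names = FALSE)
  if (anyDuplicated(all_samples))
    stop("a sample may belong to exactly one group")
  comparisons <- lapply(comparisons, function(cmp) {
    if (length(cmp) != 2L || !all(cmp %in% names(groups)))
      stop("each comparison must name two defined groups")
    cmp
  })
  structure(list(groups = groups, comparisons = comparisons),
            class = "group_design")
}

#' Differential methylation across group comparisons
#'
#' For each declared pair of groups, per-sample counts are pooled by
#' summing within each group, and a two-sided Fisher exact test is run on
#' the 2x2 table `[[Cm_1, Cu_1], [Cm_2, Cu_2]]` at every site (or
#' region). Sites with zero pooled coverage in either group are flagged
#' missing and excluded from the BH family. BH adjustment is applied
#' across all tested sites, independently per comparison.
#'
#' @param sites A [call_methylation_sites()] or [aggregate_regions()]
#'   table.
#' @param design A [group_design()].
#' @return The input table with, per comparison `g1_vs_g2`, columns
#'   `Cm_g1.<cmp>`, `Cu_g1.<cmp>`, `Cm_g2.<cmp>`, `Cu_g2.<cmp>`,
#'   `delta.<cmp>` (rate g1 - rate g2), `fisher_p.<cmp>`,
#'   `fisher_q.<cmp>`.
#' @export
diff_methylation <- function(sites, design) {
  stopifnot(inherits(design, "group_design"))
  samples <- attr(sites, "samples")
  for (g in names(design$groups)) {
    missing <- setdiff(design$groups[[g]], samples)
    if (length(missing))
      stop("group ", g, " references unknown sample(s): ",
           paste(missing, collapse = ", "))
  }
  pool <- function(group, what) {
    cols <- paste0(what, ".", design$groups[[group]])
    rowSums(as.matrix(sites[, cols, drop = FALSE]))
  }
  out <- sites
  for (cmp in design$comparisons) {
    g1 <- cmp[1]; g2 <- cmp[2]
    cname <- paste0(g1, "_vs_", g2)
    Cm1 <- pool(g1, "Cm"); Cu1 <- pool(g1, "Cu")
    Cm2 <- pool(g2, "Cm"); Cu2 <- pool(g2, "Cu")
    testable <- (Cm1 + Cu1) > 0 & (Cm2 + Cu2) > 0
    p <- rep(NA_real_, nrow(sites))
    for (i in which(testable)) {
      tab <- matrix(c(Cm1[i], Cu1[i], Cm2[i], Cu2[i]), nrow = 2,
                    byrow = TRUE)
      p[i] <- min(1, stats::fisher.test(tab)$p.value)
    }
    out[[paste0("Cm_g1.", cname)]] <- Cm1
    out[[paste0("Cu_g1.", cname)]] <- Cu1
    out[[paste0("Cm_g2.", cname)]] <- Cm2
    out[[paste0("Cu_g2.", cname)]] <- Cu2
    out[[paste0("delta.", cname)]] <-
      methylation_rate(Cm1, Cu1) - methylation_rate(Cm2, Cu2)
    out[[paste0("fisher_p.", cname)]] <- p
    out[[paste0("fisher_q.", cname)]] <- bh_adjust(p)
  }
  attr(out, "samples") <- samples
  attr(out, "comparisons") <- vapply(design$comparisons, function(cmp)
    paste0(cmp[1], "_vs_", cmp[2]), character(1))
  out
}
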