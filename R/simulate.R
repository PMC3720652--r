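# Synthetic-data generators. Every analysis module in the package is
# testable against these: each generator records the ground truth it
# sampled (methylation rates, read origins, differential-expression
# flags, filter pass/fail), so downstream estimates can be checked
# exactly or within sampling error, with no external data.

#' Simulate a random reference genome
#'
#' @param length Sequence length in bases.
#' @param gc_fraction Target G+C fraction (bases drawn i.i.d.).
#' @param seed Integer seed (mandatory; all generators are deterministic
#'   given the seed).
#' @param name Sequence name.
#' @return A named `DNAStringSet` of one sequence.
#' @export
simulate_genome <- function(length, gc_fraction = 0.5, seed, name = "chrSim") {
  stopifnot(length >= 1, gc_fraction >= 0, gc_fraction <= 1)
  set.seed(seed)
  p <- c(A = (1 - gc_fraction) / 2, C = gc_fraction / 2,
         G = gc_fraction / 2, T = (1 - gc_fraction) / 2)
  bases <- sample(names(p), length, replace = TRUE, prob = p)
  out <- Biostrings::DNAStringSet(paste(bases, collapse = ""))
  names(out) <- name
  out
}

#' Simulate a per-cytosine methylome
#'
#' Every cytosine of the genome — reference `C` (plus strand) and
#' reference `G` (the cytosine of the minus strand) — receives an
#' independent true methylation rate drawn from `rate_fun`.
#'
#' @param genome `DNAStringSet` (e.g. from [simulate_genome()]).
#' @param seed Integer seed.
#' @param rate_fun `function(n)` drawing `n` rates in `[0, 1]`; default
#'   uniform.
#' @return data.frame `chrom`, `pos` (1-based), `strand`, `rate`.
#' @export
simulate_methylome <- function(genome, seed, rate_fun = stats::runif) {
  set.seed(seed)
  out <- lapply(seq_along(genome), function(i) {
    chars <- strsplit(as.character(genome[[i]]), "", fixed = TRUE)[[1]]
    pos <- which(chars %in% c("C", "G"))
    data.frame(chrom = names(genome)[i], pos = pos,
               strand = ifelse(chars[pos] == "C", "+", "-"),
               rate = rate_fun(length(pos)), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Simulate bisulfite-converted reads with ground truth
#'
#' Error-free single-end reads of fixed length are placed uniformly over
#' each sequence, on either strand with equal probability, to a target
#' mean coverage. At every covered cytosine the emitted base is the
#' unconverted cytosine with probability equal to the site's true rate
#' (methylated molecules resist conversion) and the converted base
#' otherwise, subject to the conversion efficiency; minus-strand
#' cytosines use the complementary G/A logic in reference-forward
#' orientation. Alignments encoding the true placements are returned so
#' methylation calling is testable without running an aligner.
#'
#' @param genome `DNAStringSet`.
#' @param methylome [simulate_methylome()] output.
#' @param coverage Target mean fold-coverage.
#' @param read_length Read length in bases (default 100).
#' @param seed Integer seed.
#' @param conversion_efficiency Probability that an unmethylated
#'   cytosine is actually converted (default 1).
#' @param error_rate Uniform substitution error probability per base
#'   (default 0; the conversion chemistry itself is not an error).
#' @return List:
#'   \describe{
#'     \item{reads}{FASTQ-style data.frame (`id`, `seq`, `qual`), read
#'       sequences in sequencing orientation}
#'     \item{alignments}{coordinate-sorted SAM-style data.frame (see
#'       [read_sam()]) with `seq` in reference orientation, CIGAR
#'       `<read_length>M`, MAPQ 60}
#'     \item{truth}{data.frame `chrom`, `pos`, `Cm`, `Cu`: the exact
#'       per-site informative tallies the emitted bases carry}
#'     \item{methylome}{the input rate map}
#'     \item{n_reads}{reads simulated}
#'   }
#' @export
simulate_bisulfite_reads <- function(genome, methylome, coverage,
                                     read_length = 100L, seed,
                                     conversion_efficiency = 1.0,
                                     error_rate = 0) {
  stopifnot(coverage > 0, read_length >= 1)
  set.seed(seed)
  all_aln <- list()
  all_truth <- list()
  read_counter <- 0L
  for (ci in seq_along(genome)) {
    chrom <- names(genome)[ci]
    chars <- strsplit(as.character(genome[[ci]]), "", fixed = TRUE)[[1]]
    L <- length(chars)
    if (L < read_length)
      stop("sequence ", chrom, " shorter than read_length")
    rate_by_pos <- rep(NA_real_, L)
    msub <- methylome[methylome$chrom == chrom, , drop = FALSE]
    rate_by_pos[msub$pos] <- msub$rate
    n_reads <- ceiling(coverage * L / read_length)
    starts <- sample.int(L - read_length + 1L, n_reads, replace = TRUE)
    rev <- sample(c(FALSE, TRUE), n_reads, replace = TRUE)

    idx <- rep(starts, each = read_length) +
      rep.int(seq_len(read_length) - 1L, n_reads)
    refb <- chars[idx]
    rev_e <- rep(rev, each = read_length)
    site <- (refb == "C" & !rev_e) | (refb == "G" & rev_e)
    base <- refb
    n_site <- sum(site)
    if (n_site) {
      rate <- rate_by_pos[idx[site]]
      meth <- stats::runif(n_site) < rate
      converted <- !meth
      if (conversion_efficiency < 1)
        converted <- converted &
          (stats::runif(n_site) < conversion_efficiency)
      conv_base <- ifelse(rev_e[site], "A", "T")
      base[site][converted] <- conv_base[converted]
    }
    if (error_rate > 0) {
      err <- stats::runif(length(base)) < error_rate
      if (any(err))
        base[err] <- sample(c("A", "C", "G", "T"), sum(err),
                            replace = TRUE)
    }
    # Truth tallies from the emitted bases: exactly what a caller that
    # reads the same alignments must recover.
    is_cm <- (refb == "C" & !rev_e & base == "C") |
             (refb == "G" &  rev_e & base == "G")
    is_cu <- (refb == "C" & !rev_e & base == "T") |
             (refb == "G" &  rev_e & base == "A")
    inf <- is_cm | is_cu
    if (any(inf)) {
      cm <- rowsum(as.integer(is_cm[inf]), idx[inf])
      cu <- rowsum(as.integer(is_cu[inf]), idx[inf])
      all_truth[[chrom]] <- data.frame(
        chrom = chrom, pos = as.integer(rownames(cm)),
        Cm = as.integer(cm[, 1]), Cu = as.integer(cu[, 1]),
        stringsAsFactors = FALSE)
    }
    m <- matrix(base, nrow = read_length)
    seq_fwd <- do.call(paste0, as.data.frame(t(m),
                                             stringsAsFactors = FALSE))
    # sequencing-orientation strings for minus-strand reads
    seq_rc <- chartr("ACGT", "TGCA", do.call(
      paste0, as.data.frame(t(m[read_length:1, , drop = FALSE]),
                            stringsAsFactors = FALSE)))
    ids <- sprintf("read_%s_%d", chrom,
                   read_counter + seq_len(n_reads))
    read_counter <- read_counter + n_reads
    all_aln[[chrom]] <- data.frame(
      qname = ids, flag = ifelse(rev, 16L, 0L), rname = chrom,
      pos = starts, mapq = 60L,
      cigar = sprintf("%dM", read_length), seq = seq_fwd,
      qual = strrep("I", read_length),
      unmapped = FALSE, reverse = rev, secondary = FALSE,
      read_seq = ifelse(rev, seq_rc, seq_fwd),
      stringsAsFactors = FALSE)
  }
  aln <- do.call(rbind, all_aln)
  aln <- aln[order(aln$rname, aln$pos), , drop = FALSE]
  rownames(aln) <- NULL
  reads <- data.frame(id = aln$qname, seq = aln$read_seq,
                      qual = aln$qual, stringsAsFactors = FALSE)
  aln$read_seq <- NULL
  truth <- do.call(rbind, all_truth)
  rownames(truth) <- NULL
  list(reads = reads, alignments = aln, truth = truth,
       methylome = methylome, n_reads = nrow(aln))
}

#' Simulate a two-group expression count table with known effects
#'
#' Gene-wise baseline means are drawn log-normally around
#' `baseline_mean`; a flagged fraction of genes carries an
#' `effect_fold` change in group B. Counts are negative-binomial with
#' the given dispersion (Poisson when `dispersion = 0`).
#'
#' @param n_genes Number of genes.
#' @param group_sizes Integer vector of two group sizes (each >= 2).
#' @param baseline_mean Median baseline expression count.
#' @param effect_fold Fold change applied to flagged genes in group B;
#'   1 means no gene is flagged (a pure null table).
#' @param frac_de Fraction of genes flagged when `effect_fold != 1`.
#' @param dispersion NB dispersion (variance = mu + dispersion * mu^2).
#' @param seed Integer seed.
#' @param sdlog Log-sd of the gene baseline spread.
#' @return List: `table` (a `count_table`, see [count_fragments()]),
#'   `truth` (data.frame `gene`, `is_de`, `mean_a`, `mean_b`),
#'   `group_a`/`group_b` sample names.
#' @export
simulate_count_table <- function(n_genes, group_sizes = c(3L, 3L),
                                 baseline_mean = 50, effect_fold = 1,
                                 frac_de = 0.1, dispersion = 0.1, seed,
                                 sdlog = 1) {
  stopifnot(length(group_sizes) == 2L, all(group_sizes >= 2L))
  set.seed(seed)
  genes <- sprintf("gene_%05d", seq_len(n_genes))
  samples_a <- sprintf("A_%d", seq_len(group_sizes[1]))
  samples_b <- sprintf("B_%d", seq_len(group_sizes[2]))
  mu <- stats::rlnorm(n_genes, log(baseline_mean), sdlog)
  is_de <- if (effect_fold == 1) rep(FALSE, n_genes) else
    seq_len(n_genes) %in% sample.int(n_genes, round(frac_de * n_genes))
  mu_b <- ifelse(is_de, mu * effect_fold, mu)
  draw <- function(m, n_samp) {
    sapply(seq_len(n_samp), function(j) {
      if (dispersion <= 0) stats::rpois(length(m), m)
      else stats::rnbinom(length(m), mu = m, size = 1 / dispersion)
    })
  }
  counts <- cbind(draw(mu, group_sizes[1]), draw(mu_b, group_sizes[2]))
  dimnames(counts) <- list(genes, c(samples_a, samples_b))
  tab <- structure(
    list(counts = counts, raw_counts = counts,
         totals = colSums(counts), annotation_id = genes,
         samples = c(samples_a, samples_b)),
    class = "count_table")
  list(table = tab,
       truth = data.frame(gene = genes, is_de = is_de, mean_a = mu,
                          mean_b = mu_b, stringsAsFactors = FALSE),
       group_a = samples_a, group_b = samples_b)
}

#' Simulate contig match records straddling the annotation filters
#'
#' For each organism a known subset of samples receives at least one
#' match passing both annotation thresholds (alignment length > 150 bp,
#' E-value < 1e-6); every sample additionally receives boundary decoys
#' (lengths 149-152 crossed with E-values 1e-5 to 1e-8) whose pass/fail
#' status is recorded, so filter and summary output can be checked
#' against planted truth.
#'
#' @param n_samples Number of screened samples.
#' @param organisms Character vector of organism names.
#' @param seed Integer seed.
#' @return List: `matches` (data.frame `sample`, `contig`, `subject`,
#'   `organism`, `alignment_length`, `evalue`, `pass`),
#'   `samples`, `truth_n` (data.frame `organism`, `N`: distinct samples
#'   with a passing match).
#' @export
simulate_contig_matches <- function(n_samples, organisms, seed) {
  stopifnot(length(organisms) >= 1L, n_samples >= 1L)
  set.seed(seed)
  samples <- sprintf("sample_%02d", seq_len(n_samples))
  rows <- list()
  contig_i <- 0L
  add <- function(sample, organism, len, ev) {
    contig_i <<- contig_i + 1L
    data.frame(sample = sample,
               contig = sprintf("contig_%04d", contig_i),
               subject = gsub("\\s+", "_", organism),
               organism = organism, alignment_length = len, evalue = ev,
               pass = len > 150 & ev < 1e-6, stringsAsFactors = FALSE)
  }
  for (org in organisms) {
    hit_samples <- sample(samples, sample.int(n_samples, 1L))
    for (s in hit_samples) {
      for (k in seq_len(sample.int(3L, 1L)))
        rows[[length(rows) + 1L]] <-
          add(s, org, sample(151:500, 1L), 10^-stats::runif(1, 7, 12))
    }
  }
  boundary <- expand.grid(len = 149:152, ev = 10^-(5:8))
  for (s in samples) {
    org <- sample(organisms, 1L)
    for (r in seq_len(nrow(boundary)))
      rows[[length(rows) + 1L]] <-
        add(s, org, boundary$len[r], boundary$ev[r])
  }
  matches <- do.call(rbind, rows)
  passing <- matches[matches$pass, , drop = FALSE]
  truth_n <- stats::aggregate(list(N = passing$sample),
                              by = list(organism = passing$organism),
                              FUN = function(x) length(unique(x)))
  truth_n <- truth_n[order(-truth_n$N, truth_n$organism), , drop = FALSE]
  rownames(truth_n) <- NULL
  list(matches = matches, samples = samples, truth_n = truth_n)
}

#' Write contig matches in 13-column tabular form
#'
#' Sample id followed by the standard 12 tabular search columns;
#' readable with [read_contig_matches()].
#'
#' @param matches [simulate_contig_matches()] `$matches` table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_contig_matches <- function(matches, path) {
  n <- nrow(matches)
  lines <- sprintf(
    "%s\t%s\t%s\t%.1f\t%d\t0\t0\t1\t%d\t1\t%d\t%s\t%.1f",
    matches$sample, matches$contig, matches$subject,
    rep(98.5, n), as.integer(matches$alignment_length),
    as.integer(matches$alignment_length),
    as.integer(matches$alignment_length),
    formatC(matches$evalue, format = "e", digits = 2), rep(200.0, n))
  writeLines(lines, path)
  invisible(path)
}

#' Simulate a plain FASTQ file of random reads
#'
#' Fixture generator for the chunked execution and QC paths.
#'
#' @param n_reads Number of reads.
#' @param read_length Read length (single value or vector to mix
#'   lengths).
#' @param seed Integer seed.
#' @param id_prefix Read id prefix.
#' @return data.frame (`id`, `seq`, `qual`); write with [write_fastq()].
#' @export
simulate_fastq <- function(n_reads, read_length = 75L, seed,
                           id_prefix = "r") {
  set.seed(seed)
  lens <- if (length(read_length) == 1L)
    rep(read_length, n_reads) else
    sample(read_length, n_reads, replace = TRUE)
  seqs <- vapply(lens, function(l)
    paste(sample(c("A", "C", "G", "T"), l, replace = TRUE),
          collapse = ""), character(1))
  quals <- vapply(lens, function(l)
    paste(intToUtf8(sample(33:73, l, replace = TRUE),
                    multiple = TRUE), collapse = ""), character(1))
  data.frame(id = sprintf("%s%06d", id_prefix, seq_len(n_reads)),
             seq = seqs, qual = quals, stringsAsFactors = FALSE)
}
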