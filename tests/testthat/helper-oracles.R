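# Independent oracles used across the suite. Each reimplements the
# checked quantity from first principles, never by calling the package
# path it verifies.

# Two-sided Fisher exact p by full enumeration of tables with the same
# margins: X ~ Hypergeometric, p = sum of outcome probabilities no more
# likely than the observed one (with the conventional relative slack for
# ties).
fisher_p_enum <- function(cA, cB, TA, TB) {
  k <- cA + cB
  lo <- max(0L, k - TB)
  hi <- min(k, TA)
  probs <- dhyper(lo:hi, TA, TB, k)
  obs <- dhyper(cA, TA, TB, k)
  min(1, sum(probs[probs <= obs * (1 + 1e-7)]))
}

# Step-up BH from the definition: q_(i) = min over j >= i of m p_(j) / j.
bh_stepup <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- pmin(1, rev(cummin(rev(m * p[o] / seq_len(m)))))
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# Pooled-variance two-sample Student t from the textbook formula.
pooled_t <- function(xA, xB) {
  nA <- length(xA); nB <- length(xB)
  sp2 <- ((nA - 1) * var(xA) + (nB - 1) * var(xB)) / (nA + nB - 2)
  tstat <- (mean(xA) - mean(xB)) / sqrt(sp2 * (1 / nA + 1 / nB))
  list(t = tstat, p = 2 * pt(-abs(tstat), nA + nB - 2))
}

# Brute-force count of fragments overlapping each interval by >= 1 base.
overlap_count_brute <- function(frag_start, frag_end, ann_start, ann_end) {
  vapply(seq_along(ann_start), function(i)
    sum(frag_start <= ann_end[i] & frag_end >= ann_start[i]), numeric(1))
}

# A small deterministic FASTQ file on disk; returns its path.
write_tmp_fastq <- function(reads) {
  path <- tempfile(fileext = ".fastq")
  write_fastq(reads, path)
  path
}

# SAM data.frame row constructor for hand-built alignment fixtures.
sam_row <- function(qname, rname, pos, cigar, seq, flag = 0L) {
  data.frame(qname = qname, flag = flag, rname = rname, pos = pos,
             mapq = 60L, cigar = cigar, seq = seq,
             qual = strrep("I", nchar(seq)),
             unmapped = bitwAnd(flag, 4L) > 0L,
             reverse = bitwAnd(flag, 16L) > 0L,
             secondary = bitwAnd(flag, 256L) > 0L |
               bitwAnd(flag, 2048L) > 0L,
             stringsAsFactors = FALSE)
}
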