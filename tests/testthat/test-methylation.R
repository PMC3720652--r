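# Hand-built fixture: a tiny genome with known cytosines on both strands.
#          123456789012345
ref_seq <- "AACGTTCGGATCCAT"
ref <- Biostrings::DNAStringSet(ref_seq)
names(ref) <- "chrT"

test_that("site calling counts C/T on plus and G/A on minus cytosines", {
  # position 3 is a C (CpG: pos 4 is G). Ten forward reads cover it:
  # 7 keep C (methylated), 3 read T (converted).
  aln <- do.call(rbind, lapply(1:10, function(i) {
    base <- if (i <= 7) "C" else "T"
    sam_row(sprintf("f%02d", i), "chrT", 2,
            "4M", paste0("A", base, "GT"))
  }))
  sites <- call_methylation_sites(list(s1 = aln), ref)
  s3 <- sites[sites$pos == 3, ]
  expect_equal(s3$Cm.s1, 7)
  expect_equal(s3$Cu.s1, 3)
  expect_equal(s3$rate.s1, 0.7)
  expect_equal(s3$strand, "+")
  expect_equal(s3$context, "CpG")
})

test_that("non-informative bases at a cytosine produce no site", {
  # read carries G at the + strand C (neither C nor T): not informative;
  # covered A/T positions are never sites
  aln <- sam_row("f1", "chrT", 2, "4M", "AGGT")
  sites <- call_methylation_sites(list(s1 = aln), ref)
  expect_equal(nrow(sites[sites$pos == 3, ]), 0)
})

test_that("reverse reads interrogate minus-strand cytosines via G/A", {
  # position 9 is G, i.e. a minus-strand cytosine. A reverse-flag read
  # showing G = methylated, showing A = converted.
  aln <- rbind(
    sam_row("r1", "chrT", 8, "4M", "GGAT", flag = 16L),
    sam_row("r2", "chrT", 8, "4M", "GAAT", flag = 16L))
  sites <- call_methylation_sites(list(s1 = aln), ref)
  s9 <- sites[sites$pos == 9, ]
  expect_equal(s9$strand, "-")
  expect_equal(s9$Cm.s1, 1)
  expect_equal(s9$Cu.s1, 1)
  expect_equal(s9$rate.s1, 0.5)
  # a forward read with C/T at a minus-strand cytosine is ignored
  fwd <- sam_row("f1", "chrT", 8, "4M", "GAAT")
  sites_f <- call_methylation_sites(list(s1 = fwd), ref)
  expect_equal(nrow(sites_f[sites_f$pos == 9, ]), 0)
})

test_that("contexts are assigned from the reference on both strands", {
  #  CGT at 3: CpG(+); G at 4: CpG(-); C at 7: pos8=G -> CpG(+)
  #  G at 8: pos7=C -> CpG(-); G at 9: pos8=G, pos7=C -> CHG(-)
  #  C at 12: pos13=C, pos14=A -> CHH(+); C at 13: pos14=A,pos15=T -> CHH
  cover_all <- sam_row("f1", "chrT", 1, "15M", ref_seq)
  rev_all <- sam_row("r1", "chrT", 1, "15M", ref_seq, flag = 16L)
  sites <- call_methylation_sites(list(s1 = rbind(cover_all, rev_all)),
                                  ref)
  ctx <- setNames(sites$context, sites$pos)
  expect_equal(ctx[["3"]], "CpG")
  expect_equal(ctx[["4"]], "CpG")
  expect_equal(ctx[["7"]], "CpG")
  expect_equal(ctx[["8"]], "CpG")
  expect_equal(ctx[["9"]], "CHG")
  expect_equal(ctx[["12"]], "CHH")
  expect_equal(ctx[["13"]], "CHH")
})

test_that("unknown alignment chromosome is an error naming the sequence", {
  aln <- sam_row("f1", "chrX", 1, "4M", "AACG")
  expect_error(call_methylation_sites(list(s1 = aln), ref), "chrX")
})

test_that("methylation_rate has no pseudocount and no-calls zero coverage", {
  expect_equal(methylation_rate(10, 0), 1)
  expect_equal(methylation_rate(0, 10), 0)
  expect_equal(methylation_rate(7, 3), 0.7)
  expect_true(is.na(methylation_rate(0, 0)))
  expect_error(methylation_rate(-1, 2), "non-negative")
})

test_that("strand symmetry: reverse-complemented data mirrors the sites", {
  g <- simulate_genome(400, 0.5, seed = 101, name = "chrS")
  m <- simulate_methylome(g, seed = 102)
  sim <- simulate_bisulfite_reads(g, m, coverage = 8, read_length = 50,
                                  seed = 103)
  sites <- call_methylation_sites(list(s1 = sim$alignments), g)

  L <- Biostrings::width(g)[1]
  grc <- Biostrings::reverseComplement(g)
  names(grc) <- "chrS"
  aln <- sim$alignments
  revcomp1 <- function(s) as.character(
    Biostrings::reverseComplement(Biostrings::DNAStringSet(s)))
  mirrored <- data.frame(
    qname = aln$qname, flag = ifelse(aln$reverse, 0L, 16L),
    rname = "chrS", pos = L - (aln$pos + nchar(aln$seq) - 1L) + 1L,
    mapq = 60L, cigar = aln$cigar, seq = revcomp1(aln$seq),
    qual = aln$qual, unmapped = FALSE, reverse = !aln$reverse,
    secondary = FALSE, stringsAsFactors = FALSE)
  mirrored <- mirrored[order(mirrored$pos), ]
  sites_rc <- call_methylation_sites(list(s1 = mirrored), grc)

  expect_equal(nrow(sites_rc), nrow(sites))
  # site at pos p maps to L - p + 1 with flipped strand, same counts
  key <- function(d) order(d$pos)
  a <- sites[order(sites$pos), ]
  b <- sites_rc[order(L - sites_rc$pos + 1L), ]
  expect_equal(L - b$pos + 1L, a$pos)
  expect_equal(b$Cm.s1, a$Cm.s1)
  expect_equal(b$Cu.s1, a$Cu.s1)
  expect_equal(b$strand, ifelse(a$strand == "+", "-", "+"))
})

test_that("region aggregation pools counts, matching a brute-force oracle", {
  g <- simulate_genome(600, 0.5, seed = 111)
  m <- simulate_methylome(g, seed = 112)
  sim <- simulate_bisulfite_reads(g, m, coverage = 6, read_length = 40,
                                  seed = 113)
  sites <- call_methylation_sites(list(s1 = sim$alignments), g)
  ann <- make_annotations(data.frame(
    id = c("rA", "rB", "rEmpty"), chrom = "chrSim",
    start = c(1, 200, 10000), end = c(250, 450, 10100)))
  reg <- aggregate_regions(sites, ann)
  for (i in 1:2) {
    inside <- sites$pos >= reg$start[i] & sites$pos <= reg$end[i]
    expect_equal(reg$Cm.s1[i], sum(sites$Cm.s1[inside]))
    expect_equal(reg$Cu.s1[i], sum(sites$Cu.s1[inside]))
    expect_equal(reg$rate.s1[i],
                 sum(sites$Cm.s1[inside]) /
                   sum(sites$Cm.s1[inside] + sites$Cu.s1[inside]))
  }
  # empty region: zero counts, no-call rate
  expect_equal(reg$Cm.s1[3], 0)
  expect_true(is.na(reg$rate.s1[3]))
})

test_that("region rate is count-weighted, not a mean of site rates", {
  sites <- data.frame(chrom = "c", pos = c(10L, 20L), strand = "+",
                      context = "CpG", Cm.s1 = c(1L, 0L),
                      Cu.s1 = c(0L, 1L),
                      rate.s1 = c(1, 0), stringsAsFactors = FALSE)
  attr(sites, "samples") <- "s1"
  class(sites) <- c("methylation_sites", "data.frame")
  ann <- make_annotations(data.frame(id = "r", chrom = "c",
                                     start = 1, end = 100))
  reg <- aggregate_regions(sites, ann)
  expect_equal(reg$rate.s1, 0.5)
  # one-site region equals the site rate
  ann1 <- make_annotations(data.frame(id = "r1", chrom = "c",
                                      start = 1, end = 15))
  expect_equal(aggregate_regions(sites, ann1)$rate.s1, 1)
})

test_that("group designs enforce the 10-group cap and membership rules", {
  expect_error(group_design(setNames(as.list(letters[1:11]),
                                     LETTERS[1:11]), list()),
               "10 groups")
  expect_error(group_design(list(a = "s1", b = "s1"), list()),
               "exactly one group")
  expect_error(group_design(list(a = "s1", b = "s2"),
                            list(c("a", "zzz"))), "defined groups")
  d <- group_design(list(a = c("s1", "s2"), b = c("s3")),
                    list(c("a", "b")))
  expect_s3_class(d, "group_design")
})

test_that("differential methylation pools within groups per comparison", {
  sites <- data.frame(
    chrom = "c", pos = c(5L, 10L, 15L), strand = "+", context = "CpG",
    Cm.s1 = c(6L, 10L, 0L), Cu.s1 = c(4L, 0L, 0L),
    rate.s1 = c(0.6, 1, NA),
    Cm.s2 = c(4L, 10L, 0L), Cu.s2 = c(6L, 0L, 0L),
    rate.s2 = c(0.4, 1, NA),
    Cm.s3 = c(1L, 0L, 5L), Cu.s3 = c(9L, 10L, 5L),
    rate.s3 = c(0.1, 0, 0.5), stringsAsFactors = FALSE)
  attr(sites, "samples") <- c("s1", "s2", "s3")
  class(sites) <- c("methylation_sites", "data.frame")
  design <- group_design(list(ctl = c("s1", "s2"), ind = "s3"),
                         list(c("ctl", "ind")))
  dm <- diff_methylation(sites, design)
  cmp <- "ctl_vs_ind"
  # pooled counts
  expect_equal(dm[[paste0("Cm_g1.", cmp)]], c(10, 20, 0))
  expect_equal(dm[[paste0("Cu_g1.", cmp)]], c(10, 0, 0))
  # site 1: 10/10 vs 1/9 -> fisher on [[10,10],[1,9]]
  expect_equal(dm[[paste0("fisher_p.", cmp)]][1],
               fisher.test(matrix(c(10, 10, 1, 9), 2,
                                  byrow = TRUE))$p.value)
  # identical pooled proportions give p = 1
  sites2 <- sites
  sites2$Cm.s3 <- c(5L, 10L, 0L); sites2$Cu.s3 <- c(5L, 0L, 0L)
  dm2 <- diff_methylation(sites2, design)
  expect_equal(dm2[[paste0("fisher_p.", cmp)]][1], 1)
  # extreme table equals the enumeration oracle
  sites3 <- sites
  sites3$Cm.s1 <- c(10L, 0L, 0L); sites3$Cu.s1 <- c(0L, 0L, 0L)
  sites3$Cm.s2 <- c(0L, 0L, 0L); sites3$Cu.s2 <- c(0L, 0L, 0L)
  sites3$Cm.s3 <- c(0L, 0L, 0L); sites3$Cu.s3 <- c(10L, 0L, 0L)
  dm3 <- diff_methylation(sites3, design)
  expect_equal(dm3[[paste0("fisher_p.", cmp)]][1],
               fisher_p_enum(10, 0, 10, 10))
  # site with zero pooled coverage in one group: flagged missing,
  # excluded from the BH family
  expect_true(is.na(dm[[paste0("fisher_p.", cmp)]][3]))
  tested <- !is.na(dm[[paste0("fisher_p.", cmp)]])
  expect_equal(dm[[paste0("fisher_q.", cmp)]][tested],
               bh_stepup(dm[[paste0("fisher_p.", cmp)]][tested]))
})

test_that("multiple comparisons yield independent statistic columns", {
  sites <- data.frame(
    chrom = "c", pos = 5L, strand = "+", context = "CpG",
    Cm.s1 = 8L, Cu.s1 = 2L, rate.s1 = 0.8,
    Cm.s2 = 2L, Cu.s2 = 8L, rate.s2 = 0.2,
    Cm.s3 = 5L, Cu.s3 = 5L, rate.s3 = 0.5, stringsAsFactors = FALSE)
  attr(sites, "samples") <- c("s1", "s2", "s3")
  class(sites) <- c("methylation_sites", "data.frame")
  design <- group_design(list(a = "s1", b = "s2", c = "s3"),
                         list(c("a", "b"), c("a", "c")))
  dm <- diff_methylation(sites, design)
  expect_true(all(c("fisher_p.a_vs_b", "fisher_q.a_vs_b",
                    "fisher_p.a_vs_c", "fisher_q.a_vs_c") %in% names(dm)))
  expect_equal(dm$delta.a_vs_b, 0.6)
  expect_equal(dm$delta.a_vs_c, 0.3)
})
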