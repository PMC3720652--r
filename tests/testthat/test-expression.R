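make_ann <- function(starts, ends, chrom = "chr1") {
  make_annotations(data.frame(
    id = sprintf("ann%02d", seq_along(starts)),
    chrom = chrom, start = starts, end = ends))
}

test_that("fragment counting matches the brute-force overlap oracle", {
  set.seed(23)
  for (rep in 1:5) {
    n_frag <- 50
    starts <- sort(sample.int(900, n_frag, replace = TRUE))
    widths <- sample(10:60, n_frag, replace = TRUE)
    aln <- do.call(rbind, lapply(seq_len(n_frag), function(i)
      sam_row(sprintf("r%03d", i), "chr1", starts[i],
              sprintf("%dM", widths[i]), strrep("A", widths[i]))))
    a_start <- sample.int(900, 8)
    a_end <- a_start + sample(5:120, 8, replace = TRUE)
    ann <- make_ann(a_start, a_end)
    tab <- count_fragments(list(s1 = aln), ann)
    brute <- overlap_count_brute(starts, starts + widths - 1,
                                 a_start, a_end)
    expect_equal(unname(tab$counts[, "s1"]), brute)
    expect_equal(unname(tab$totals["s1"]), n_frag)
  }
})

test_that("a fragment in two overlapping annotations is counted in both", {
  aln <- sam_row("r1", "chr1", 100, "20M", strrep("A", 20))
  ann <- make_ann(c(90, 110), c(150, 160))
  tab <- count_fragments(list(s1 = aln), ann)
  expect_equal(unname(tab$counts[, "s1"]), c(1, 1))
})

test_that("zero reads give zero counts; unsorted input is refused", {
  ann <- make_ann(1, 100)
  empty <- sam_row("x", "chr1", 1, "5M", "AAAAA")[0, ]
  tab <- count_fragments(list(s1 = empty), ann)
  expect_equal(unname(tab$counts[, "s1"]), 0)
  expect_equal(unname(tab$totals["s1"]), 0L)

  unsorted <- rbind(sam_row("r1", "chr1", 500, "5M", "AAAAA"),
                    sam_row("r2", "chr1", 10, "5M", "AAAAA"))
  expect_error(count_fragments(list(s1 = unsorted), ann), "sort")
})

test_that("secondary records are ignored and unit weights are neutral", {
  aln <- rbind(sam_row("r1", "chr1", 10, "10M", strrep("A", 10)),
               sam_row("r1", "chr1", 50, "10M", strrep("A", 10),
                       flag = 256L))
  ann <- make_ann(c(1, 40), c(30, 70))
  tab <- count_fragments(list(s1 = aln), ann)
  expect_equal(unname(tab$counts[, "s1"]), c(1, 0))
  expect_equal(unname(tab$totals["s1"]), 1L)

  w <- list(s1 = c(r1 = 1))
  tabw <- count_fragments(list(s1 = aln), ann, weights = w)
  expect_equal(tabw$counts, tab$counts)

  w2 <- list(s1 = c(r1 = 0.25))
  tabw2 <- count_fragments(list(s1 = aln), ann, weights = w2)
  expect_equal(unname(tabw2$counts[, "s1"]), c(0.25, 0))
  expect_equal(tabw2$raw_counts, tab$raw_counts)  # raw stays integer
})

test_that("with well-separated annotations counts never exceed totals", {
  set.seed(31)
  starts <- sort(sample.int(500, 40, replace = TRUE))
  aln <- do.call(rbind, lapply(seq_along(starts), function(i)
    sam_row(sprintf("r%03d", i), "chr1", starts[i], "20M",
            strrep("A", 20))))
  # gaps wider than the fragment length: no fragment spans two
  ann <- make_ann(seq(1, 501, by = 125), seq(100, 600, by = 125))
  tab <- count_fragments(list(s1 = aln), ann)
  expect_lte(sum(tab$counts[, "s1"]), unname(tab$totals["s1"]))
})

test_that("junction counting enumerates alignment gaps", {
  # one skip gap
  a1 <- sam_row("r1", "chr1", 100, "10M50N10M", strrep("A", 20))
  j1 <- count_junction_reads(a1)
  expect_equal(nrow(j1), 1)
  expect_equal(j1$donor, 110)
  expect_equal(j1$acceptor, 159)
  expect_equal(j1$count, 1)

  # ungapped contributes nothing
  expect_equal(nrow(count_junction_reads(
    sam_row("r2", "chr1", 5, "20M", strrep("A", 20)))), 0)

  # two skip gaps in one read increment both junctions; a second read
  # sharing the first junction stacks on it
  a3 <- rbind(
    sam_row("r3", "chr1", 100, "10M50N10M30N5M", strrep("A", 25)),
    sam_row("r4", "chr1", 95, "15M50N10M", strrep("A", 25)))
  j3 <- count_junction_reads(a3)
  expect_equal(nrow(j3), 2)
  expect_equal(j3$count[j3$donor == 110], 2)
  expect_equal(j3$count[j3$donor == 170], 1)  # 100 +10M +50N +10M
})

test_that("rpkm follows the printed closed form and its monotonicity", {
  expect_equal(rpkm(0, 1000, 1e6), 1)
  expect_equal(rpkm(9, 500, 2e6), 10)
  expect_equal(rpkm(999, 1000, 1e6), 1000)
  # monotone in each argument
  expect_gt(rpkm(10, 1000, 1e6), rpkm(5, 1000, 1e6))
  expect_lt(rpkm(10, 2000, 1e6), rpkm(10, 1000, 1e6))
  expect_lt(rpkm(10, 1000, 2e6), rpkm(10, 1000, 1e6))
  expect_error(rpkm(1, 0, 1e6), "positive")
  expect_error(rpkm(1, 1000, 0), "positive")
  # log2 always finite thanks to the +1 pseudocount
  expect_true(is.finite(log2(rpkm(0, 10, 1e9))))
})

test_that("normalization factors: totals and nearest-rank upper quartile", {
  counts <- matrix(c(1:100, rep(0, 100)), ncol = 2,
                   dimnames = list(sprintf("g%d", 1:100), c("s1", "s2")))
  counts[1:100, 2] <- c(rep(0, 50), 1:50)
  tab <- structure(list(counts = counts, raw_counts = counts,
                        totals = c(s1 = 2e6, s2 = 5e5),
                        annotation_id = rownames(counts),
                        samples = c("s1", "s2")),
                   class = "count_table")
  N_tot <- normalization_factor(tab, "total")
  expect_equal(unname(N_tot), c(2e6, 5e5))

  N_uq <- normalization_factor(tab, "upper-quartile")
  # brute-force nearest-rank oracle on nonzero counts
  uq <- function(x) {
    x <- sort(x[x > 0])
    unname(x[ceiling(0.75 * length(x))])
  }
  expect_equal(unname(N_uq["s1"]), uq(counts[, 1]))
  expect_equal(unname(N_uq["s2"]), uq(counts[, 2]))

  # single-annotation table: the quartile is that count
  tab1 <- structure(list(
    counts = matrix(7, dimnames = list("g1", "s1")),
    raw_counts = matrix(7L, dimnames = list("g1", "s1")),
    totals = c(s1 = 7L), annotation_id = "g1", samples = "s1"),
    class = "count_table")
  expect_equal(unname(normalization_factor(tab1, "upper-quartile")), 7)

  # all-zero sample: factor undefined
  tab0 <- tab1
  tab0$counts[] <- 0
  expect_error(normalization_factor(tab0, "upper-quartile"), "s1")
})

test_that("heptamer weights recover the start/distal frequency ratio", {
  # constructed set: heptamer H is 2x over-represented at read starts
  # relative to the distal window -> weight 0.5; heptamer K balanced -> 1
  H <- "ACGTACG"
  K <- "TTTTAAA"
  pad <- function(first, distal) {
    # read: first heptamer, filler to position 24, then the distal
    # window content repeated across positions 24..30
    paste0(first, strrep("C", 16), strrep(distal, 3))  # length 44
  }
  reads <- data.frame(
    id = sprintf("r%02d", 1:4),
    seq = c(pad(H, K), pad(H, K), pad(K, H), pad(K, H)),
    qual = strrep("I", 44), stringsAsFactors = FALSE)
  # start frequencies: H 0.5, K 0.5. Distal heptamers at 24..30 of
  # "KKKK..." repeats differ; compute the oracle ratio directly.
  k <- 7
  starts <- substr(reads$seq, 1, k)
  distal <- unlist(lapply(24:30, function(p) substr(reads$seq, p, p + 6)))
  f_start <- table(starts) / length(starts)
  f_distal <- table(distal) / length(distal)
  w <- heptamer_weights(reads)
  for (i in 1:4) {
    h <- starts[i]
    fd <- if (h %in% names(f_distal)) f_distal[[h]] else 0
    expect_equal(unname(w[reads$id[i]]), fd / f_start[[h]])
  }
})

test_that("unbiased reads give weights near 1", {
  # two-letter alphabet keeps the heptamer space (2^7) densely sampled,
  # so both frequency estimates are stable and their ratio should sit
  # near 1 when start and distal compositions are identical
  set.seed(91)
  reads <- data.frame(
    id = sprintf("r%04d", 1:2000),
    seq = vapply(1:2000, function(i)
      paste(sample(c("A", "C"), 40, replace = TRUE), collapse = ""),
      character(1)),
    qual = strrep("I", 40), stringsAsFactors = FALSE)
  w <- heptamer_weights(reads)
  expect_lt(abs(mean(w) - 1), 0.1)
  expect_true(all(w > 0))
})

test_that("short reads get weight 1 with a warning", {
  reads <- data.frame(id = "s", seq = strrep("A", 20),
                      qual = strrep("I", 20))
  expect_warning(w <- heptamer_weights(reads), "shorter")
  expect_equal(unname(w), 1)
})

test_that("diff_expression assembles a coherent per-annotation report", {
  sim <- simulate_count_table(200, c(3L, 3L), baseline_mean = 80,
                              effect_fold = 4, frac_de = 0.2,
                              dispersion = 0, seed = 55)
  ann <- make_annotations(data.frame(
    id = sim$table$annotation_id, chrom = "chr1",
    start = seq(1, by = 2000, length.out = 200),
    end = seq(1000, by = 2000, length.out = 200)))
  de <- diff_expression(sim$table, ann, sim$group_a, sim$group_b)
  expect_equal(nrow(de), 200)
  expect_true(all(de$fisher_p >= 0 & de$fisher_p <= 1))
  expect_true(all(de$fisher_q >= de$fisher_p))
  expect_true(all(de$ttest_q >= de$ttest_p, na.rm = TRUE))
  expect_true(all(is.finite(as.matrix(
    de[, grep("^log2rpkm", names(de))]))))
  # flagged genes should dominate the smallest fisher q-values
  top <- order(de$fisher_q)[1:20]
  expect_gt(mean(sim$truth$is_de[top]), 0.8)
})
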