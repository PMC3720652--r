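#' Two-sided Fisher exact test on raw fragment counts
#'
#' Tests whether the proportion of a sample group's fragments falling in
#' one annotation differs between two groups, on the 2x2 table
#' `[[cA, TA - cA], [cB, TB - cB]]` where `cA`/`cB` are pooled annotation
#' counts and `TA`/`TB` pooled totals of aligned fragments.
#'
#' @param cA,cB Annotation counts in groups A and B (non-negative
#'   integers).
#' @param TA,TB Total aligned fragments in groups A and B; `TA >= cA`,
#'   `TB >= cB`.
#' @return Two-sided p-value.
#' @export
fisher_exact_de <- function(cA, cB, TA, TB) {
  vals <- c(cA, cB, TA, TB)
  if (any(vals < 0) || any(vals != round(vals)))
    stop("counts and totals must be non-negative integers")
  if (TA < cA || TB < cB)
    stop("totals must be at least as large as counts")
  tab <- matrix(c(cA, TA - cA, cB, TB - cB), nrow = 2, byrow = TRUE)
  # guard against p = 1 + eps from floating-point accumulation
  min(1, stats::fisher.test(tab)$p.value)
}

#' Pooled-variance Student t test on log2 expression
#'
#' Classic (non-moderated, equal-variance) two-sample Student t on the
#' per-sample `log2(RPKM)` values of one annotation.
#'
#' @param xA,xB Numeric vectors of `log2(RPKM)` per sample, one per
#'   group; each group needs at least 2 samples.
#' @return List with `t` (statistic, group A minus group B) and `p`
#'   (two-sided); both `NA` (flagged missing, never 0) when a group has
#'   fewer than 2 samples or the pooled variance is zero.
#' @export
ttest_de <- function(xA, xB) {
  if (length(xA) < 2L || length(xB) < 2L)
    return(list(t = NA_real_, p = NA_real_))
  if (stats::var(xA) == 0 && stats::var(xB) == 0) {
    if (isTRUE(all.equal(mean(xA), mean(xB))))
      return(list(t = 0, p = 1))
    return(list(t = NA_real_, p = NA_real_))
  }
  fit <- stats::t.test(xA, xB, var.equal = TRUE)
  list(t = unname(fit$statistic), p = fit$p.value)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up FDR adjustment; `NA` entries are passed through and
#' do not count toward the family size.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (NAs allowed).
#' @return Adjusted values (q-values), elementwise `>= p` and `<= 1`.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Two-group differential expression over annotations
#'
#' The full per-annotation report: counts, RPKM and log2(RPKM) per
#' sample, group mean log2(RPKM), fold change, a Fisher exact test on
#' pooled raw counts, a pooled-variance Student t test on log2(RPKM),
#' and BH-adjusted q-values for both statistics. The Fisher test always
#' uses unweighted integer counts even when the table holds weighted
#' counts.
#'
#' @param count_table A [count_fragments()] result.
#' @param annotations The `GRanges` the table was counted over (supplies
#'   lengths `L`).
#' @param group_a,group_b Character vectors of sample names.
#' @param norm `"total"` or `"upper-quartile"` (see
#'   [normalization_factor()]).
#' @return data.frame with one row per annotation: `id`, `length`,
#'   `count.<sample>`, `rpkm.<sample>`, `log2rpkm.<sample>`,
#'   `mean_log2_rpkm_a`, `mean_log2_rpkm_b`, `log2_fold_change`,
#'   `fold_change`, `fisher_p`, `ttest_p`, `fisher_q`, `ttest_q`.
#' @export
diff_expression <- function(count_table, annotations, group_a, group_b,
                            norm = c("total", "upper-quartile")) {
  norm <- match.arg(norm)
  samples <- count_table$samples
  stopifnot(all(group_a %in% samples), all(group_b %in% samples),
            length(intersect(group_a, group_b)) == 0L)
  ids <- count_table$annotation_id
  stopifnot(identical(ids, annotations$id))
  L <- GenomicRanges::width(annotations)
  N <- normalization_factor(count_table, norm)

  r <- sapply(samples, function(s)
    rpkm(count_table$counts[, s], L, N[s]))
  if (is.null(dim(r))) r <- matrix(r, nrow = length(ids),
                                   dimnames = list(ids, samples))
  lr <- log2(r)

  cA <- rowSums(count_table$raw_counts[, group_a, drop = FALSE])
  cB <- rowSums(count_table$raw_counts[, group_b, drop = FALSE])
  TA <- sum(count_table$totals[group_a])
  TB <- sum(count_table$totals[group_b])
  fisher_p <- vapply(seq_along(ids), function(i)
    fisher_exact_de(cA[i], cB[i], TA, TB), numeric(1))
  tres <- lapply(seq_along(ids), function(i)
    ttest_de(lr[i, group_a], lr[i, group_b]))
  ttest_p <- vapply(tres, `[[`, numeric(1), "p")

  mean_a <- rowMeans(lr[, group_a, drop = FALSE])
  mean_b <- rowMeans(lr[, group_b, drop = FALSE])
  out <- data.frame(id = ids, length = L, stringsAsFactors = FALSE)
  for (s in samples) out[[paste0("count.", s)]] <- count_table$counts[, s]
  for (s in samples) out[[paste0("rpkm.", s)]] <- r[, s]
  for (s in samples) out[[paste0("log2rpkm.", s)]] <- lr[, s]
  out$mean_log2_rpkm_a <- mean_a
  out$mean_log2_rpkm_b <- mean_b
  out$log2_fold_change <- mean_a - mean_b
  out$fold_change <- 2^(mean_a - mean_b)
  out$fisher_p <- fisher_p
  out$ttest_p <- ttest_p
  out$fisher_q <- bh_adjust(fisher_p)
  out$ttest_q <- bh_adjust(ttest_p)
  rownames(out) <- NULL
  out
}
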