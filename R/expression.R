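#' Median-of-ratios size factors
#'
#' Per-sample normalization constants correcting for sequencing depth.
#' Reference genes are those with nonzero counts in every sample; the
#' factor of sample s is the median over reference genes of
#' count(g, s) / geometric mean of gene g across samples.
#'
#' @param counts an `ma_counts` object or a numeric matrix.
#' @return named numeric vector of positive size factors.
#' @export
size_factors <- function(counts) {
  m <- if (inherits(counts, "ma_counts")) counts$counts else as.matrix(counts)
  ref <- rowSums(m > 0) == ncol(m)
  if (!any(ref))
    stopf("no reference gene: every gene has a zero count in some sample")
  logm <- log(m[ref, , drop = FALSE])
  geo <- rowMeans(logm)
  sf <- apply(exp(logm - geo), 2, stats::median)
  stats::setNames(sf, colnames(m))
}

# counts divided by their size factors
normalized_counts <- function(counts, sf = NULL) {
  m <- if (inherits(counts, "ma_counts")) counts$counts else as.matrix(counts)
  if (is.null(sf)) sf <- size_factors(m)
  sweep(m, 2, sf, "/")
}

#' FPKM normalization
#'
#' Fragments per kilobase of exon per million mapped fragments:
#' \eqn{count \cdot 10^9 / (length \cdot library)} with library the
#' sample's total mapped counts.
#'
#' @param counts an `ma_counts` object or matrix.
#' @param exonic_lengths bp per gene, named or in row order.
#' @return matrix of FPKM values.
#' @export
fpkm <- function(counts, exonic_lengths) {
  m <- if (inherits(counts, "ma_counts")) counts$counts else as.matrix(counts)
  if (!is.null(names(exonic_lengths)))
    exonic_lengths <- exonic_lengths[rownames(m)]
  if (any(is.na(exonic_lengths) | exonic_lengths <= 0))
    stopf("exonic lengths must be positive for every gene")
  lib <- colSums(m)
  if (any(lib == 0)) stopf("zero library size in sample(s): %s",
                           paste(colnames(m)[lib == 0], collapse = ", "))
  m * 1e9 / outer(as.numeric(exonic_lengths), lib)
}

#' Drop the most weakly expressed genes
#'
#' Genes are ranked by the mean normalized count across all samples of
#' their strain (the minimum over strains is the filter statistic, so a
#' gene is kept only if it clears the bar in some strain); the
#' bottom-ranked genes are dropped so that about `target_retained` of
#' genes remain.
#'
#' @param counts an `ma_counts` object.
#' @param target_retained fraction of genes to keep, in (0, 1].
#' @return a filtered `ma_counts` object.
#' @export
filter_low_counts <- function(counts, target_retained = 0.95) {
  if (!(target_retained > 0 && target_retained <= 1))
    stopf("target_retained must be in (0, 1]")
  if (target_retained == 1) return(counts)
  nc <- normalized_counts(counts)
  stat <- apply(
    vapply(unique(counts$samples$strain), function(s) {
      rowMeans(nc[, counts$samples$strain == s, drop = FALSE])
    }, numeric(nrow(nc))), 1, max)
  n_keep <- round(target_retained * nrow(nc))
  keep <- rank(-stat, ties.method = "first") <= n_keep
  out <- counts
  out$counts <- counts$counts[keep, , drop = FALSE]
  out$gene_ids <- rownames(out$counts)
  out
}

#' Replicate quality control by expression correlation
#'
#' For each replicate, the mean Pearson correlation of its FPKM profile
#' with its sibling replicates of the same line. Replicates below
#' `threshold` are flagged; per the analysis contract they are excluded
#' from mean-based summaries but retained for DEG calling.
#'
#' @param fpkm_mat FPKM matrix (genes x samples).
#' @param samples sample metadata with sample_id and line_id.
#' @param threshold minimum acceptable mean correlation.
#' @return data.frame: sample_id, line_id, mean_r, flagged, reason.
#' @export
replicate_qc <- function(fpkm_mat, samples, threshold = 0.96) {
  out <- lapply(split(samples$sample_id, samples$line_id), function(ids) {
    if (length(ids) < 2)
      stopf("line with fewer than 2 replicates: %s",
            samples$line_id[match(ids[1], samples$sample_id)])
    sub <- fpkm_mat[, ids, drop = FALSE]
    sds <- apply(sub, 2, stats::sd)
    r <- suppressWarnings(stats::cor(sub))
    vapply(seq_along(ids), function(i) {
      if (sds[i] == 0) return(NA_real_)
      mean(r[i, -i][sds[-i] > 0], na.rm = TRUE)
    }, numeric(1)) -> mean_r
    data.frame(sample_id = ids,
               line_id = samples$line_id[match(ids, samples$sample_id)],
               mean_r = mean_r,
               flagged = is.na(mean_r) | mean_r < threshold,
               reason = ifelse(is.na(mean_r), "constant expression",
                               ifelse(mean_r < threshold, "low correlation", "")),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Directional sums of significant expression change
#'
#' Per line, the sum of positive and (separately) negative log2 fold
#' changes over significant DEGs, plus the DEG count: the per-line
#' transcriptome divergence summaries used for the divergence scatter
#' and the fitness regressions.
#'
#' @param degs a data.frame of DEG records (multiple lines allowed) as
#'   produced by [call_degs()].
#' @return data.frame: line_id, n_degs, sum_pos, sum_neg,
#'   sum_abs_log2fc.
#' @export
directional_change_sums <- function(degs) {
  sp <- split(degs, degs$line_id)
  out <- lapply(names(sp), function(l) {
    d <- sp[[l]][sp[[l]]$significant, ]
    data.frame(line_id = l, n_degs = nrow(d),
               sum_pos = sum(d$log2fc[d$log2fc > 0]),
               sum_neg = sum(d$log2fc[d$log2fc < 0]),
               sum_abs_log2fc = sum(abs(d$log2fc)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
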