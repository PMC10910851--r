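#' Distance from each DEG to the nearest mutation of its line
#'
#' Intragenic mutations (anywhere in the gene body: UTRs, exons,
#' introns) are assigned a distance of 1; otherwise the distance is the
#' minimum bp gap between the mutation position and the nearer gene
#' flank, minimized over the line's mutations. Coordinates are 0-based
#' half-open.
#'
#' @param deg_genes character vector of DEG gene ids (one line).
#' @param mutations data.frame with `chrom` and `pos` for the same line.
#' @param annotation an `ma_annotation`.
#' @return named numeric vector of distances (Inf when the line has no
#'   mutation on a DEG's chromosome).
#' @export
nearest_mutation_distance <- function(deg_genes, mutations, annotation) {
  miss <- setdiff(deg_genes, annotation$gene_id)
  if (length(miss))
    stopf("gene(s) absent from annotation: %s", paste(miss, collapse = ", "))
  idx <- match(deg_genes, annotation$gene_id)
  out <- vapply(idx, function(i) {
    g <- annotation[i, ]
    mu <- mutations[mutations$chrom == g$chrom, , drop = FALSE]
    if (!nrow(mu)) return(Inf)
    inside <- mu$pos >= g$start & mu$pos < g$end
    if (any(inside)) return(1)
    min(pmax(g$start - mu$pos, mu$pos - g$end))
  }, numeric(1))
  stats::setNames(out, deg_genes)
}

# add-one permutation p-value: b permutations at least as extreme
perm_pvalue <- function(b, n_perm) (b + 1) / (n_perm + 1)

#' Permutation test for cis-acting mutation proximity
#'
#' Tests whether a line's DEGs sit unusually close to its mutations.
#' The statistic is the number of DEGs with a mutation within `window`
#' bp of the gene flanks (intragenic mutations count). The null keeps
#' mutation positions fixed and redraws which genes are labelled DEGs,
#' uniformly from the gene universe, so an enrichment of DEGs near
#' mutations is distinguished from mutations simply being near genes.
#'
#' @param deg_genes DEG gene ids of one line.
#' @param mutations the line's mutations (`chrom`, `pos`).
#' @param annotation an `ma_annotation`.
#' @param window proximity window in bp.
#' @param n_perm permutation draws.
#' @param seed integer seed.
#' @return list: `observed` (DEGs with a nearby mutation),
#'   `observed_mutations` (mutations within `window` of a DEG — the
#'   companion count), `p` (add-one permutation p), `significant`
#'   (p < 0.05), `marginal` (0.05 <= p < 0.1), `n_perm`.
#' @export
cis_enrichment_test <- function(deg_genes, mutations, annotation,
                                window = 100, n_perm = 10000, seed = 1L) {
  if (!length(deg_genes) || is.null(mutations) || !nrow(mutations))
    stopf("need >= 1 DEG and >= 1 mutation")
  if (length(deg_genes) > nrow(annotation))
    stopf("more DEGs than genes in the universe")
  near <- gene_near_mutation(mutations, annotation, window)
  idx <- match(deg_genes, annotation$gene_id)
  if (anyNA(idx)) stopf("DEG gene(s) missing from annotation")
  obs <- sum(near[idx])
  set.seed(child_seed(seed, 30L))
  k <- length(deg_genes)
  perm <- vapply(seq_len(n_perm), function(i) sum(near[sample.int(length(near), k)]),
                 numeric(1))
  p <- perm_pvalue(sum(perm >= obs), n_perm)
  # companion count: mutations within `window` of any DEG
  obs_mut <- mutations_near_genes(mutations, annotation[idx, , drop = FALSE], window)
  list(observed = obs, observed_mutations = obs_mut, p = p,
       significant = p < 0.05, marginal = p >= 0.05 & p < 0.1, n_perm = n_perm)
}

# logical per gene: any mutation within `window` bp of the gene span
gene_near_mutation <- function(mutations, annotation, window) {
  gr_gene <- GenomicRanges::GRanges(annotation$chrom,
    IRanges::IRanges(start = annotation$start + 1 - window,
                     end = annotation$end + window))
  gr_mut <- GenomicRanges::GRanges(mutations$chrom,
    IRanges::IRanges(start = mutations$pos + 1, width = 1))
  IRanges::overlapsAny(gr_gene, gr_mut)
}

mutations_near_genes <- function(mutations, genes, window) {
  gr_gene <- GenomicRanges::GRanges(genes$chrom,
    IRanges::IRanges(start = genes$start + 1 - window,
                     end = genes$end + window))
  gr_mut <- GenomicRanges::GRanges(mutations$chrom,
    IRanges::IRanges(start = mutations$pos + 1, width = 1))
  sum(IRanges::overlapsAny(gr_mut, gr_gene))
}

#' UTR enrichment of intragenic mutations
#'
#' Fold enrichment of UTR placement among mutations inside gene bodies:
#' the fraction of intragenic mutations falling in annotated UTR bp,
#' divided by the UTR fraction of the denominator sequence space —
#' total gene-model bp by default, or the whole genome with
#' `denominator = "genome"`.
#'
#' @param mutations data.frame with `chrom`, `pos` (any number of
#'   lines pooled).
#' @param annotation an `ma_annotation`.
#' @param denominator `"gene_model"` or `"genome"`.
#' @return list: `fold`, `n_intragenic`, `n_utr`, `utr_fraction`
#'   (of the denominator space).
#' @export
utr_enrichment <- function(mutations, annotation,
                           denominator = c("gene_model", "genome")) {
  denominator <- match.arg(denominator)
  utr_bp <- sum(annotation$utr5_end - annotation$utr5_start) +
    sum(annotation$utr3_end - annotation$utr3_start)
  if (utr_bp == 0) stopf("annotation has no UTR bp")
  denom_bp <- if (denominator == "gene_model") {
    sum(annotation$end - annotation$start)
  } else {
    cl <- attr(annotation, "chrom_lengths")
    if (is.null(cl)) stopf("genome denominator needs chrom_lengths")
    sum(cl)
  }
  gr_mut <- GenomicRanges::GRanges(mutations$chrom,
    IRanges::IRanges(start = mutations$pos + 1, width = 1))
  gr_gene <- GenomicRanges::GRanges(annotation$chrom,
    IRanges::IRanges(start = annotation$start + 1, end = annotation$end))
  gr_utr <- c(
    GenomicRanges::GRanges(annotation$chrom,
      IRanges::IRanges(start = annotation$utr5_start + 1, end = annotation$utr5_end)),
    GenomicRanges::GRanges(annotation$chrom,
      IRanges::IRanges(start = annotation$utr3_start + 1, end = annotation$utr3_end)))
  intragenic <- IRanges::overlapsAny(gr_mut, gr_gene)
  if (!any(intragenic)) stopf("no intragenic mutation")
  in_utr <- IRanges::overlapsAny(gr_mut, gr_utr) & intragenic
  utr_fraction <- utr_bp / denom_bp
  fold <- (sum(in_utr) / sum(intragenic)) / utr_fraction
  list(fold = fold, n_intragenic = sum(intragenic), n_utr = sum(in_utr),
       utr_fraction = utr_fraction)
}

#' Permutation test for SV-DEG overlap
#'
#' A gene is SV-overlapped when its model interval intersects any of
#' the line's structural-variant intervals by at least 1 bp. The
#' statistic is the proportion of SV-overlapped genes that are DEGs;
#' the null redraws DEG sets of the same size uniformly from the gene
#' universe.
#'
#' @param svs the line's SVs (`chrom`, `start`, `end`); duplicated
#'   records are collapsed by set semantics.
#' @param deg_genes DEG gene ids of the line.
#' @param annotation an `ma_annotation`.
#' @param n_perm permutation draws.
#' @param seed integer seed.
#' @return list: `proportion` (observed), `n_overlapped`, `p`,
#'   `significant`, `n_perm`.
#' @export
sv_deg_overlap_test <- function(svs, deg_genes, annotation,
                                n_perm = 1000, seed = 1L) {
  if (!is.null(svs) && nrow(svs)) {
    if (any(svs$start >= svs$end)) stopf("malformed SV interval (start >= end)")
  }
  hit <- overlapped_genes(svs, annotation)
  if (!length(hit))
    return(list(proportion = 0, n_overlapped = 0L, p = 1,
                significant = FALSE, n_perm = n_perm))
  is_deg <- annotation$gene_id %in% deg_genes
  hit_idx <- match(hit, annotation$gene_id)
  obs <- mean(is_deg[hit_idx])
  set.seed(child_seed(seed, 31L))
  k <- length(unique(deg_genes))
  n_genes <- nrow(annotation)
  perm <- vapply(seq_len(n_perm), function(i) {
    mean(hit_idx %in% sample.int(n_genes, k))
  }, numeric(1))
  p <- perm_pvalue(sum(perm >= obs), n_perm)
  list(proportion = obs, n_overlapped = length(hit), p = p,
       significant = p < 0.05, n_perm = n_perm)
}
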