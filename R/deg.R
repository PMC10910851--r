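#' Call differentially expressed genes for one MA line
#'
#' Simplified negative-binomial Wald test of one MA line against the
#' unmutated ancestor of its strain. Per gene a two-group NB GLM with
#' log link and size-factor offsets is fitted by maximum likelihood at a
#' fixed, moment-estimated dispersion shrunk toward a mean-dispersion
#' trend; the line-vs-ancestor coefficient is tested with a Wald z
#' statistic and p-values are Benjamini-Hochberg adjusted across the
#' genes tested.
#'
#' This caller deliberately implements only the analysis contract
#' (Wald test, BH, FDR threshold) rather than the full machinery of a
#' production DE package; externally produced DEG tables in the same
#' schema can be substituted anywhere downstream.
#'
#' @param counts an `ma_counts` object (typically after
#'   [filter_low_counts()]).
#' @param line_id MA line to test.
#' @param alpha FDR threshold for the `significant` flag.
#' @param sf optional precomputed size factors for all samples.
#' @param pseudocount added to normalized group means when reporting
#'   log2 fold changes if either mean is zero.
#' @param prior_df weight (in residual degrees of freedom) of the
#'   dispersion trend in the shrunk per-gene dispersion.
#' @return data.frame of DEG records: line_id, gene_id, log2fc, p,
#'   p_adj, significant, direction.
#' @export
call_degs <- function(counts, line_id, alpha = 0.05, sf = NULL,
                      pseudocount = 0.5, prior_df = 5) {
  smp <- counts$samples
  if (!line_id %in% smp$line_id) stopf("unknown line: %s", line_id)
  strain <- smp$strain[smp$line_id == line_id][1]
  anc_ids <- smp$sample_id[smp$strain == strain & smp$is_ancestor]
  line_ids <- smp$sample_id[smp$line_id == line_id]
  if (length(anc_ids) < 2 || length(line_ids) < 2)
    stopf("need >= 2 replicates in both the line and its ancestor")
  if (is.null(sf)) sf <- size_factors(counts)
  y <- counts$counts[, c(anc_ids, line_ids), drop = FALSE]
  s <- sf[c(anc_ids, line_ids)]
  grp <- rep(c(0L, 1L), c(length(anc_ids), length(line_ids)))
  disp <- estimate_dispersions(y, s, grp, prior_df = prior_df)
  res <- nb_two_group_wald(y, s, grp, disp, pseudocount = pseudocount)
  p_adj <- stats::p.adjust(res$p, method = "BH")
  data.frame(line_id = line_id, gene_id = rownames(y),
             log2fc = res$log2fc, p = res$p, p_adj = p_adj,
             significant = p_adj < alpha,
             direction = ifelse(res$log2fc >= 0, "up", "down"),
             stringsAsFactors = FALSE)
}

#' Call DEGs for every MA line
#'
#' @inheritParams call_degs
#' @return one combined data.frame of DEG records.
#' @export
call_degs_all <- function(counts, alpha = 0.05, ...) {
  sf <- size_factors(counts)
  lines <- unique(counts$samples$line_id[!counts$samples$is_ancestor])
  out <- lapply(lines, function(l) call_degs(counts, l, alpha = alpha, sf = sf, ...))
  do.call(rbind, out)
}

# Method-of-moments NB dispersions with shrinkage toward a 1/mu trend.
# Normalized counts have Var ~ mu * E(1/sf) + alpha * mu^2; the gene-wise
# estimate is pooled across the two groups and then averaged with the
# trend value, weighting the gene estimate by its residual df.
estimate_dispersions <- function(y, s, grp, prior_df = 5, min_disp = 1e-8) {
  nc <- sweep(y, 2, s, "/")
  xi <- mean(1 / s)
  groups <- split(seq_along(grp), grp)
  nobs <- length(grp)
  ss <- Reduce(`+`, lapply(groups, function(ix) {
    sub <- nc[, ix, drop = FALSE]
    rowSums((sub - rowMeans(sub))^2)
  }))
  df <- nobs - length(groups)
  v <- ss / df
  mu <- rowMeans(nc)
  raw <- pmax((v - xi * mu) / mu^2, 0)
  raw[!is.finite(raw)] <- 0
  # trend alpha(mu) = a0 + a1/mu fitted to genes with informative estimates
  use <- raw > 0 & mu > 0
  a0 <- 0.01; a1 <- 1
  if (sum(use) >= 10) {
    fit <- stats::lm(raw[use] ~ I(1 / mu[use]))
    a0 <- max(unname(stats::coef(fit)[1]), 1e-4)
    a1 <- max(unname(stats::coef(fit)[2]), 0)
  } else if (sum(use) >= 2) {
    a0 <- stats::median(raw[use])
    a1 <- 0
  }
  trend <- a0 + a1 / pmax(mu, 1e-8)
  pmax((df * raw + prior_df * trend) / (df + prior_df), min_disp)
}

# Exact two-group NB GLM Wald test, vectorized across genes. With a
# saturated two-group mean structure the MLE solves, per group g,
# sum_s (y_s - sf_s m_g) / (1 + alpha sf_s m_g) = 0 (1-D Newton), and
# the Wald variance of the log ratio is 1/I_A + 1/I_L with
# I_g = sum_s sf_s m_g / (1 + alpha sf_s m_g).
nb_two_group_wald <- function(y, s, grp, disp, pseudocount = 0.5) {
  fit_group <- function(ix) {
    sub <- y[, ix, drop = FALSE]
    sg <- s[ix]
    m <- rowSums(sub) / sum(sg)     # Poisson MLE as the start
    ay <- sweep(sub, 1, disp, "*")  # alpha_g * y_gs
    for (it in 1:50) {
      M <- outer(m, sg)
      denom <- 1 + sweep(M, 1, disp, "*")
      f <- rowSums((sub - M) / denom)
      fp <- -rowSums(sweep(1 + ay, 2, sg, "*") / denom^2)
      m_new <- pmax(m - f / fp, 0)
      if (max(abs(m_new - m) / pmax(m, 1e-8)) < 1e-10) { m <- m_new; break }
      m <- m_new
    }
    M <- outer(m, sg)
    info <- rowSums(M / (1 + sweep(M, 1, disp, "*")))
    list(m = m, info = info)
  }
  a <- fit_group(which(grp == 0L))
  b <- fit_group(which(grp == 1L))
  mean_sf <- mean(s)
  mA <- a$m; mL <- b$m
  zero <- mA == 0 | mL == 0
  log2fc <- ifelse(zero,
                   log2((mL + pseudocount / mean_sf) /
                          (mA + pseudocount / mean_sf)),
                   log2(mL / mA))
  # floor the Fisher information of an all-zero group so SEs stay finite
  infoA <- pmax(a$info, pseudocount)
  infoL <- pmax(b$info, pseudocount)
  se_ln <- sqrt(1 / infoA + 1 / infoL)
  z <- (log2fc * log(2)) / se_ln
  p <- 2 * stats::pnorm(-abs(z))
  p[mA == 0 & mL == 0] <- 1
  list(log2fc = log2fc, p = p, z = z)
}
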