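#' Expression percentile bins
#'
#' Assigns each gene to one of `n_bins` equal-size rank bins of its
#' (typically ancestral FPKM) expression level; bin 1 holds the lowest
#' expression. Ties are broken by stable input order, so labels are
#' invariant under strictly monotone transforms of the values.
#'
#' @param values named per-gene expression levels.
#' @param n_bins number of bins.
#' @return integer vector of bin labels (named like `values`); bin
#'   sizes differ by at most 1.
#' @export
percentile_bins <- function(values, n_bins = 10) {
  n <- length(values)
  if (n < n_bins) stopf("fewer genes (%d) than bins (%d)", n, n_bins)
  r <- rank(values, ties.method = "first")
  bins <- as.integer(floor((r - 1) * n_bins / n) + 1)
  stats::setNames(bins, names(values))
}

#' Median expression change by percentile bin
#'
#' Per gene, the median log2 fold change across MA lines; summarized
#' per bin.
#'
#' @param bins per-gene bin labels from [percentile_bins()].
#' @param log2fc_table data.frame with `gene_id`, `line_id`, `log2fc`
#'   (all lines of a strain).
#' @return list: `per_gene` (gene_id, bin, median_log2fc), `per_bin`
#'   (bin, median, q25, q75, n_genes).
#' @export
median_change_by_bin <- function(bins, log2fc_table) {
  med <- tapply(log2fc_table$log2fc, log2fc_table$gene_id, stats::median)
  common <- intersect(names(bins), names(med))
  per_gene <- data.frame(gene_id = common,
                         bin = unname(bins[common]),
                         median_log2fc = unname(med[common]),
                         stringsAsFactors = FALSE)
  per_bin <- do.call(rbind, lapply(sort(unique(per_gene$bin)), function(b) {
    v <- per_gene$median_log2fc[per_gene$bin == b]
    data.frame(bin = b, median = stats::median(v),
               q25 = unname(stats::quantile(v, 0.25)),
               q75 = unname(stats::quantile(v, 0.75)),
               n_genes = length(v))
  }))
  list(per_gene = per_gene, per_bin = per_bin)
}

#' Brunner-Munzel rank test
#'
#' Studentized rank statistic for the stochastic-superiority hypothesis
#' \eqn{P(X < Y) + \frac12 P(X = Y) = \frac12}, with
#' Satterthwaite-approximated degrees of freedom and a two-sided
#' t-approximation p-value. Robust to unequal variances and ties.
#'
#' @param x,y numeric samples (each of size >= 2).
#' @return list: `statistic`, `df`, `p`, `superiority` (the estimate of
#'   \eqn{P(X<Y) + \frac12 P(X=Y)}), `n_x`, `n_y`.
#' @export
brunner_munzel <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2 || n2 < 2) stopf("both samples need >= 2 observations")
  r <- rank(c(x, y))
  rx <- r[seq_len(n1)]; ry <- r[n1 + seq_len(n2)]
  m1 <- mean(rx); m2 <- mean(ry)
  ix <- rank(x); iy <- rank(y)
  v1 <- sum((rx - ix - m1 + (n1 + 1) / 2)^2) / (n1 - 1)
  v2 <- sum((ry - iy - m2 + (n2 + 1) / 2)^2) / (n2 - 1)
  superiority <- (m2 - (n2 + 1) / 2) / n1
  if (v1 == 0 && v2 == 0) {
    if (m1 == m2)  # identical rank profiles: no evidence either way
      return(list(statistic = 0, df = NA_real_, p = 1,
                  superiority = superiority, n_x = n1, n_y = n2))
    # complete separation: superiority 0 or 1, variance degenerate
    return(list(statistic = sign(m2 - m1) * Inf, df = NA_real_, p = 0,
                superiority = superiority, n_x = n1, n_y = n2))
  }
  if (v1 == 0 || v2 == 0)
    stopf("degenerate rank variance in sample %s", if (v1 == 0) "x" else "y")
  stat <- n1 * n2 * (m2 - m1) / (n1 + n2) / sqrt(n1 * v1 + n2 * v2)
  df <- (n1 * v1 + n2 * v2)^2 /
    ((n1 * v1)^2 / (n1 - 1) + (n2 * v2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(stat), df)
  list(statistic = stat, df = df, p = p, superiority = superiority,
       n_x = n1, n_y = n2)
}

#' Fitness versus expression divergence
#'
#' Ordinary least-squares regression of relative fitness on a per-line
#' divergence summary (DEG count or summed |log2fc|), with a
#' systematic leave-one-out influence report: the slope, R-squared and
#' p-value of the refit without each line.
#'
#' @param table data.frame with `line_id`, `fitness_rel` and the
#'   predictor column.
#' @param predictor `"n_degs"` or `"sum_abs_log2fc"` (any numeric
#'   column name is accepted).
#' @return list: `slope`, `intercept`, `r_squared`, `p`, `n`,
#'   `leave_one_out` (line_id, slope, r_squared, p without that line).
#' @export
fitness_regression <- function(table, predictor = c("n_degs", "sum_abs_log2fc")) {
  predictor <- if (length(predictor) == 1) predictor else match.arg(predictor)
  if (!predictor %in% names(table)) stopf("no column '%s'", predictor)
  if (nrow(table) < 3) stopf("need >= 3 lines")
  x <- table[[predictor]]; y <- table$fitness_rel
  if (stats::sd(x) == 0) stopf("constant predictor")
  ols <- function(xx, yy) {
    fit <- stats::lm(yy ~ xx)
    sm <- summary(fit)
    c(slope = unname(stats::coef(fit)[2]),
      intercept = unname(stats::coef(fit)[1]),
      r_squared = sm$r.squared,
      p = unname(sm$coefficients[2, 4]))
  }
  full <- ols(x, y)
  loo <- do.call(rbind, lapply(seq_len(nrow(table)), function(i) {
    if (stats::sd(x[-i]) == 0)
      return(data.frame(line_id = table$line_id[i], slope = NA,
                        r_squared = NA, p = NA))
    f <- ols(x[-i], y[-i])
    data.frame(line_id = table$line_id[i], slope = f[["slope"]],
               r_squared = f[["r_squared"]], p = f[["p"]],
               stringsAsFactors = FALSE)
  }))
  list(slope = full[["slope"]], intercept = full[["intercept"]],
       r_squared = full[["r_squared"]], p = full[["p"]], n = nrow(table),
       leave_one_out = loo)
}
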