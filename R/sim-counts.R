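#' Simulate a read-count matrix from an experiment truth
#'
#' For gene j in sample s the count is drawn as
#' \eqn{Poisson(sf_s \exp(\mu_j + \delta_{j,line(s)} + b_s))}: a
#' log-normal ancestral level \eqn{\mu_j}, the line's true log effect
#' \eqn{\delta} (0 in ancestors; `effect_log2 * log(2)` otherwise), an
#' observation-level normal effect \eqn{b_s} creating extra-Poisson
#' dispersion, and a library size factor. Each strain contributes
#' `replicates` ancestral samples alongside its MA lines.
#'
#' @param truth an [generate_truth()] result.
#' @param annotation the matching annotation.
#' @return an object of class `ma_counts`: list with integer matrix
#'   `counts` (genes x samples), `samples` metadata data.frame
#'   (sample_id, strain, line_id, replicate, is_ancestor, generations,
#'   n_mutations, true_size_factor), and `gene_ids`.
#' @export
generate_counts <- function(truth, annotation) {
  cfg <- truth$config
  set.seed(child_seed(cfg$seed, 3L))
  n_genes <- nrow(annotation)
  mu <- stats::rnorm(n_genes, cfg$baseline_log_mean, cfg$baseline_log_sd)
  names(mu) <- annotation$gene_id

  anc <- data.frame(
    line_id = sprintf("S%d_ANC", seq_len(cfg$n_strains)),
    strain = sprintf("S%d", seq_len(cfg$n_strains)),
    generations = 0, n_mutations = 0L,
    is_ancestor = TRUE, stringsAsFactors = FALSE
  )
  ma <- data.frame(
    line_id = truth$lines$line_id, strain = truth$lines$strain,
    generations = truth$lines$generations,
    n_mutations = truth$lines$n_mutations,
    is_ancestor = FALSE, stringsAsFactors = FALSE
  )
  units <- rbind(anc, ma)
  samples <- units[rep(seq_len(nrow(units)), each = cfg$replicates), ]
  samples$replicate <- rep(seq_len(cfg$replicates), nrow(units))
  samples$sample_id <- sprintf("%s_r%d", samples$line_id, samples$replicate)
  rownames(samples) <- NULL
  ns <- nrow(samples)
  sf <- stats::runif(ns, cfg$size_factor_range[1], cfg$size_factor_range[2])
  b <- stats::rnorm(ns, 0, cfg$olre_sd)
  samples$true_size_factor <- sf

  delta <- matrix(0, n_genes, nrow(units),
                  dimnames = list(annotation$gene_id, units$line_id))
  if (nrow(truth$effects)) {
    idx <- cbind(match(truth$effects$gene_id, annotation$gene_id),
                 match(truth$effects$line_id, units$line_id))
    keep <- stats::complete.cases(idx)
    delta[idx[keep, , drop = FALSE]] <- truth$effects$effect_log2[keep] * log(2)
  }
  lam <- exp(outer(mu, rep(0, ns), "+") +
               delta[, match(samples$line_id, units$line_id), drop = FALSE] +
               matrix(b, n_genes, ns, byrow = TRUE)) *
    matrix(sf, n_genes, ns, byrow = TRUE)
  counts <- matrix(stats::rpois(length(lam), lam), n_genes, ns,
                   dimnames = list(annotation$gene_id, samples$sample_id))
  out <- list(counts = counts,
              samples = samples[, c("sample_id", "strain", "line_id", "replicate",
                                    "is_ancestor", "generations", "n_mutations",
                                    "true_size_factor")],
              gene_ids = annotation$gene_id)
  class(out) <- "ma_counts"
  validate_ma_counts(out)
  out
}

#' Assemble a count object from raw pieces
#'
#' @param counts nonnegative integer matrix, genes x samples.
#' @param samples metadata with at least sample_id, strain, line_id,
#'   replicate, is_ancestor; rows must match `colnames(counts)`.
#' @return an `ma_counts` object.
#' @export
ma_counts <- function(counts, samples) {
  out <- list(counts = as.matrix(counts), samples = as.data.frame(samples),
              gene_ids = rownames(counts))
  class(out) <- "ma_counts"
  validate_ma_counts(out)
  out
}

validate_ma_counts <- function(x) {
  if (anyDuplicated(rownames(x$counts))) stopf("duplicate gene ids")
  if (anyDuplicated(x$samples$sample_id)) stopf("duplicate sample ids")
  if (!identical(colnames(x$counts), x$samples$sample_id))
    stopf("sample metadata rows must match count matrix columns")
  if (any(!is.finite(x$counts)) || any(x$counts < 0))
    stopf("counts must be finite and nonnegative")
  ma <- x$samples[!x$samples$is_ancestor, ]
  anc_strains <- unique(x$samples$strain[x$samples$is_ancestor])
  if (nrow(ma) && !all(ma$strain %in% anc_strains))
    stopf("every MA line needs an ancestor of the same strain")
  invisible(x)
}

#' @export
print.ma_counts <- function(x, ...) {
  cat(sprintf("MA count matrix: %d genes x %d samples (%d lines, %d strains)\n",
              nrow(x$counts), ncol(x$counts),
              length(unique(x$samples$line_id[!x$samples$is_ancestor])),
              length(unique(x$samples$strain))))
  invisible(x)
}

#' Run the full generative model in one call
#'
#' @param cfg a [sim_config()].
#' @return list with `annotation`, `truth` and `counts`.
#' @export
simulate_experiment <- function(cfg) {
  annotation <- generate_annotation(cfg)
  truth <- generate_truth(cfg, annotation)
  counts <- generate_counts(truth, annotation)
  list(annotation = annotation, truth = truth, counts = counts)
}

#' Simulate counts for one gene under the mutational-variance model
#'
#' Generative form of the per-gene Poisson mixed model used by
#' [fit_gene_glmm()]: \eqn{\log \lambda = \beta_0 + \beta_1 x_i + u_i x_i
#' + b_k + \log sf}, with per-line slope \eqn{u_i \sim N(0, \sigma^2_u)}
#' and observation-level \eqn{b_k \sim N(0, \sigma^2_b)}. Used for
#' parameter-recovery checks of the variance components.
#'
#' @param n_lines,replicates design size.
#' @param x per-line covariate (generations or mutation count), length
#'   `n_lines`; recycled if scalar.
#' @param beta0,beta1 fixed intercept and slope.
#' @param sigma2_u variance of the per-line random slope.
#' @param sigma2_b observation-level (overdispersion) variance.
#' @param size_factors per-sample size factors (default 1).
#' @return data.frame with columns count, line, x, size_factor.
#' @export
simulate_glmm_gene <- function(n_lines, replicates, x, beta0, beta1 = 0,
                               sigma2_u = 0, sigma2_b = 0,
                               size_factors = NULL) {
  x <- rep_len(x, n_lines)
  u <- stats::rnorm(n_lines, 0, sqrt(sigma2_u))
  n <- n_lines * replicates
  line <- rep(seq_len(n_lines), each = replicates)
  sf <- if (is.null(size_factors)) rep(1, n) else rep_len(size_factors, n)
  b <- stats::rnorm(n, 0, sqrt(sigma2_b))
  eta <- beta0 + (beta1 + u[line]) * x[line] + b + log(sf)
  data.frame(count = stats::rpois(n, exp(eta)),
             line = factor(sprintf("L%02d", line)),
             x = x[line], size_factor = sf)
}
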