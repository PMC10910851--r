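#' Simulate module-structured expression for network tests
#'
#' Gene expression over `n_obs` observations (e.g. time points) with a
#' block-correlation structure: genes in the same module load on a
#' shared latent factor so that the expected within-module correlation
#' is `cor_within` and the between-module correlation is
#' `cor_between` (via a weak global factor).
#'
#' @param n_genes,n_modules,n_obs dimensions.
#' @param cor_within expected correlation of two genes sharing a module.
#' @param cor_between expected correlation of two genes in different
#'   modules.
#' @param seed integer seed.
#' @return list: `expr` (genes x observations matrix), `module`
#'   (integer vector, named by gene).
#' @export
simulate_module_expression <- function(n_genes, n_modules, n_obs,
                                       cor_within = 0.9, cor_between = 0.1,
                                       seed = 1L) {
  stopifnot(cor_within >= cor_between, cor_between >= 0, cor_within < 1)
  set.seed(child_seed(seed, 50L))
  module <- rep_len(seq_len(n_modules), n_genes)
  global <- stats::rnorm(n_obs)
  factors <- matrix(stats::rnorm(n_modules * n_obs), n_modules, n_obs)
  a_g <- sqrt(cor_between)
  a_m <- sqrt(cor_within - cor_between)
  a_e <- sqrt(1 - cor_within)
  noise <- matrix(stats::rnorm(n_genes * n_obs), n_genes, n_obs)
  expr <- a_g * matrix(global, n_genes, n_obs, byrow = TRUE) +
    a_m * factors[module, , drop = FALSE] + a_e * noise
  rownames(expr) <- sprintf("g%05d", seq_len(n_genes))
  list(expr = expr, module = stats::setNames(module, rownames(expr)))
}
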