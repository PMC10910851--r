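#' Configuration for a synthetic mutation accumulation experiment
#'
#' Collects every parameter of the generative model behind
#' [generate_annotation()], [generate_truth()] and [generate_counts()].
#' Defaults mirror the design of the *Chlamydomonas reinhardtii* MA panel
#' the pipeline targets: two ancestral strains carrying 15 and 13 derived
#' MA lines, three biological replicates per line, 800--1,100 generations
#' of propagation, and strain means of 76.2 and 112.1 accumulated
#' mutations per line. The per-mutation distribution of expression
#' effects (DEE) defaults to the zero-spike shifted gamma with
#' \eqn{\pi_0 = 0.42}, shape 0.0118 and scale 2,005, under which a single
#' mutation perturbs on average 14.3 genes.
#'
#' @param n_strains number of ancestral strains.
#' @param lines_per_strain integer vector, MA lines derived per strain.
#' @param replicates biological replicates per line (ancestors included).
#' @param n_genes number of gene models in the toy genome.
#' @param chrom_lengths chromosome lengths in bp.
#' @param generations_range range the per-line generation count is drawn
#'   from (uniformly).
#' @param mean_mutations_per_line per-strain Poisson mean of the number of
#'   accumulated mutations per line.
#' @param dee_pi0 probability a mutation perturbs no gene.
#' @param dee_pi1 extra point mass at exactly one perturbed gene (the
#'   three-component DEE model); 0 gives the two-component model.
#' @param dee_shape,dee_scale gamma parameters of the shifted-gamma tail:
#'   a non-null mutation perturbs \eqn{1 + \Gamma(shape, scale)} genes,
#'   rounded to the nearest integer with minimum 1.
#' @param cis_fraction fraction of single-target mutations placed within
#'   100 bp of the gene they perturb (the cis-acting fraction).
#' @param n_modules number of synthetic co-expression modules; a
#'   multi-target (trans) mutation draws its targets from one module.
#' @param effect_sd_log2 standard deviation of the signed log2 expression
#'   shift a perturbed gene receives.
#' @param baseline_log_mean,baseline_log_sd natural-log mean/sd of the
#'   log-normal ancestral expression level.
#' @param olre_sd standard deviation of the per-observation log-scale
#'   random effect (extra-Poisson overdispersion).
#' @param size_factor_range range library size factors are drawn from.
#' @param sv_per_line Poisson mean of structural variants per line.
#' @param sv_effect_prob probability a gene overlapped by a structural
#'   variant receives an expression effect.
#' @param fitness_slope change in relative fitness per distinct
#'   mutation-affected gene (non-positive).
#' @param fitness_noise_sd measurement noise on relative fitness.
#' @param seed master seed; all stages derive child seeds from it.
#'
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_strains = 2L,
                       lines_per_strain = c(15L, 13L),
                       replicates = 3L,
                       n_genes = 1000L,
                       chrom_lengths = c(2e6, 2e6),
                       generations_range = c(800, 1100),
                       mean_mutations_per_line = c(76.2, 112.1),
                       dee_pi0 = 0.42,
                       dee_pi1 = 0,
                       dee_shape = 0.0118,
                       dee_scale = 2005,
                       cis_fraction = 0.2,
                       n_modules = 20L,
                       effect_sd_log2 = 1.5,
                       baseline_log_mean = 4,
                       baseline_log_sd = 1.2,
                       olre_sd = 0.2,
                       size_factor_range = c(0.7, 1.4),
                       sv_per_line = 30,
                       sv_effect_prob = 0.5,
                       fitness_slope = -1e-3,
                       fitness_noise_sd = 0.1,
                       seed = 1L) {
  cfg <- list(
    n_strains = as.integer(n_strains),
    lines_per_strain = as.integer(rep_len(lines_per_strain, n_strains)),
    replicates = as.integer(replicates),
    n_genes = as.integer(n_genes),
    chrom_lengths = as.numeric(chrom_lengths),
    generations_range = as.numeric(generations_range),
    mean_mutations_per_line = rep_len(as.numeric(mean_mutations_per_line), n_strains),
    dee_pi0 = dee_pi0, dee_pi1 = dee_pi1,
    dee_shape = dee_shape, dee_scale = dee_scale,
    cis_fraction = cis_fraction,
    n_modules = as.integer(n_modules),
    effect_sd_log2 = effect_sd_log2,
    baseline_log_mean = baseline_log_mean,
    baseline_log_sd = baseline_log_sd,
    olre_sd = olre_sd,
    size_factor_range = as.numeric(size_factor_range),
    sv_per_line = sv_per_line,
    sv_effect_prob = sv_effect_prob,
    fitness_slope = fitness_slope,
    fitness_noise_sd = fitness_noise_sd,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  probs <- c(dee_pi0 = cfg$dee_pi0, dee_pi1 = cfg$dee_pi1,
             cis_fraction = cfg$cis_fraction, sv_effect_prob = cfg$sv_effect_prob)
  bad <- probs < 0 | probs > 1
  if (any(bad))
    stopf("probabilities out of [0,1]: %s", paste(names(probs)[bad], collapse = ", "))
  if (cfg$dee_pi0 + cfg$dee_pi1 > 1)
    stopf("dee_pi0 + dee_pi1 must be <= 1 (got %.3f)", cfg$dee_pi0 + cfg$dee_pi1)
  if (cfg$n_strains < 1L || any(cfg$lines_per_strain < 0L))
    stopf("strain and line counts must be positive")
  if (cfg$replicates < 1L) stopf("replicates must be >= 1")
  if (cfg$n_genes < 0L) stopf("n_genes must be >= 0")
  if (any(cfg$chrom_lengths <= 0)) stopf("chrom_lengths must be positive")
  if (cfg$dee_shape <= 0 || cfg$dee_scale <= 0)
    stopf("dee_shape and dee_scale must be > 0")
  if (cfg$fitness_slope > 0) stopf("fitness_slope must be <= 0")
  if (diff(cfg$generations_range) < 0 || diff(cfg$size_factor_range) < 0)
    stopf("ranges must be (lo, hi) with lo <= hi")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic MA experiment configuration\n")
  cat(sprintf("  %d strain(s); lines per strain: %s; %d replicates\n",
              x$n_strains, paste(x$lines_per_strain, collapse = ", "),
              x$replicates))
  cat(sprintf("  %d genes on %d chromosome(s) (%.3g bp total)\n",
              x$n_genes, length(x$chrom_lengths), sum(x$chrom_lengths)))
  cat(sprintf("  mutations/line (mean): %s; generations %g-%g\n",
              paste(x$mean_mutations_per_line, collapse = ", "),
              x$generations_range[1], x$generations_range[2]))
  cat(sprintf("  DEE: pi0=%.3g pi1=%.3g shape=%.3g scale=%.3g (mean %.2f DEGs/mutation)\n",
              x$dee_pi0, x$dee_pi1, x$dee_shape, x$dee_scale,
              (1 - x$dee_pi0 - x$dee_pi1) * (1 + x$dee_shape * x$dee_scale) + x$dee_pi1))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}
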