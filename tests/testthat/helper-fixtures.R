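# Shared small fixtures, built once per test run.

small_cfg <- function(seed = 3, ...) {
  defaults <- list(n_genes = 300, lines_per_strain = c(4, 3),
                   chrom_lengths = c(1e6, 1e6),
                   mean_mutations_per_line = c(20, 30), seed = seed)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

# memoized default small experiment
small_sim_env <- new.env()
small_sim <- function() {
  if (is.null(small_sim_env$sim)) small_sim_env$sim <- simulate_experiment(small_cfg())
  small_sim_env$sim
}

# hand-rolled truth object for controlled count simulations
manual_truth <- function(cfg, line_ids, strain, generations, n_mutations,
                         effects) {
  lines <- data.frame(line_id = line_ids, strain = strain,
                      generations = generations, n_mutations = n_mutations,
                      fitness_rel = 1, stringsAsFactors = FALSE)
  tr <- list(config = cfg, lines = lines, mutations = NULL, targets = NULL,
             effects = effects, svs = NULL,
             modules = data.frame(gene_id = character(0), module = integer(0)))
  class(tr) <- "ma_truth"
  tr
}

# one-line experiment with chosen true log2 effects; returns counts + truth
effect_experiment <- function(n_genes, effect_genes, effect_log2, seed,
                              olre_sd = 0.15, baseline_log_mean = 4.5,
                              baseline_log_sd = 1) {
  cfg <- sim_config(n_strains = 1, lines_per_strain = 1, n_genes = n_genes,
                    chrom_lengths = 1e7, mean_mutations_per_line = 0,
                    olre_sd = olre_sd, baseline_log_mean = baseline_log_mean,
                    baseline_log_sd = baseline_log_sd, sv_per_line = 0,
                    seed = seed)
  ann <- generate_annotation(cfg)
  eff <- if (length(effect_genes)) {
    data.frame(line_id = "S1_L01", gene_id = ann$gene_id[effect_genes],
               effect_log2 = rep_len(effect_log2, length(effect_genes)),
               stringsAsFactors = FALSE)
  } else {
    data.frame(line_id = character(0), gene_id = character(0),
               effect_log2 = numeric(0))
  }
  tr <- manual_truth(cfg, "S1_L01", "S1", 900, 50L, eff)
  list(counts = generate_counts(tr, ann), annotation = ann, truth = tr)
}

# draw per-line DEG totals from a zero-spike shifted-gamma DEE
draw_dee_totals <- function(m, pi0, shape, scale) {
  j <- stats::rbinom(length(m), m, 1 - pi0)
  g <- ifelse(j > 0, stats::rgamma(length(m), shape = j * shape, scale = scale), 0)
  round(j + g)
}
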