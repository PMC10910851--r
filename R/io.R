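#' Write a complete plain-text fixture directory
#'
#' Serializes a simulated experiment to the on-disk schema the pipeline
#' reads: `counts.tsv` (gene x sample), `samples.tsv`,
#' `annotation.gff3`, `mutations.tsv`, `svs.tsv`, `fitness.tsv` and
#' `truth.json`.
#'
#' @param sim result of [simulate_experiment()].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_experiment <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(x, f) utils::write.table(
    x, file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  cnt <- data.frame(gene_id = rownames(sim$counts$counts),
                    sim$counts$counts, check.names = FALSE)
  tsv(cnt, "counts.tsv")
  tsv(sim$counts$samples, "samples.tsv")
  write_annotation_gff3(sim$annotation, file.path(dir, "annotation.gff3"))
  tr <- sim$truth
  if (!is.null(tr$mutations)) tsv(tr$mutations, "mutations.tsv")
  if (!is.null(tr$svs)) tsv(tr$svs, "svs.tsv")
  tsv(tr$lines[, c("line_id", "fitness_rel")], "fitness.tsv")
  write_truth_json(tr, file.path(dir, "truth.json"))
  invisible(dir)
}

#' Read a count matrix with sample metadata
#'
#' @param counts_path TSV with a `gene_id` column then one column per sample.
#' @param samples_path TSV of sample metadata.
#' @return an `ma_counts` object.
#' @export
read_counts <- function(counts_path, samples_path) {
  cnt <- utils::read.delim(counts_path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  m <- as.matrix(cnt[, -1, drop = FALSE])
  rownames(m) <- cnt$gene_id
  storage.mode(m) <- "integer"
  samples <- utils::read.delim(samples_path, stringsAsFactors = FALSE)
  ma_counts(m[, samples$sample_id, drop = FALSE], samples)
}

#' Read per-line tables (mutations, SVs, fitness, DEE line summaries)
#'
#' Thin TSV readers for the documented schemas.
#' @param path file path.
#' @return a data.frame.
#' @export
read_mutations <- function(path) utils::read.delim(path, stringsAsFactors = FALSE)

#' @rdname read_mutations
#' @export
read_svs <- function(path) utils::read.delim(path, stringsAsFactors = FALSE)

#' @rdname read_mutations
#' @export
read_fitness <- function(path) utils::read.delim(path, stringsAsFactors = FALSE)

#' DEE fit JSON round trip
#'
#' Serializes the fitted parameters and information criteria of a
#' [fit_dee()] result (the line summaries are not stored).
#'
#' @param fit a `dee_fit`.
#' @param path file path.
#' @return `read_dee_fit` returns a `dee_fit` usable with [dee_mean()],
#'   [dee_category_probs()] and [simulate_deg_counts()].
#' @export
write_dee_fit <- function(fit, path) {
  payload <- fit[c("model_kind", "pi0", "pi1", "shape", "scale",
                   "loglik", "aic", "bic", "n_lines")]
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' @rdname write_dee_fit
#' @export
read_dee_fit <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- list(model_kind = p$model_kind, pi0 = p$pi0 %||% 0,
              pi1 = p$pi1 %||% 0, shape = p$shape, scale = p$scale,
              loglik = p$loglik %||% NA_real_, aic = p$aic %||% NA_real_,
              bic = p$bic %||% NA_real_,
              n_lines = if (is.null(p$n_lines)) NA_integer_
                        else as.integer(p$n_lines),
              pi0_interval = NULL, ok = TRUE, lines = NULL)
  class(out) <- "dee_fit"
  out
}

#' Truth JSON round trip
#'
#' @param truth an `ma_truth`.
#' @param path file path.
#' @return `read_truth_json` returns an `ma_truth` equal (up to class
#'   bookkeeping) to the one written.
#' @export
write_truth_json <- function(truth, path) {
  payload <- list(
    config = unclass(truth$config),
    lines = truth$lines,
    mutations = truth$mutations,
    targets = truth$targets,
    effects = truth$effects,
    svs = truth$svs,
    modules = truth$modules
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

#' @rdname write_truth_json
#' @export
read_truth_json <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- p$config
  int_fields <- c("n_strains", "lines_per_strain", "replicates", "n_genes",
                  "n_modules", "seed")
  for (f in int_fields) cfg[[f]] <- as.integer(cfg[[f]])
  class(cfg) <- "sim_config"
  fix <- function(df) {
    if (is.null(df) || (is.data.frame(df) && !nrow(df))) return(df)
    as.data.frame(df, stringsAsFactors = FALSE)
  }
  truth <- list(config = cfg, lines = fix(p$lines),
                mutations = fix(p$mutations), targets = fix(p$targets),
                effects = fix(p$effects), svs = fix(p$svs),
                modules = fix(p$modules))
  class(truth) <- "ma_truth"
  truth
}
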