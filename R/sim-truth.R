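#' Simulate the mutational truth of an MA experiment
#'
#' Draws, for every MA line, its generation count, its de novo mutations
#' and their per-mutation expression effects from the configured
#' distribution of expression effects (DEE), structural variants, and a
#' relative fitness declining with the number of distinct affected genes.
#'
#' Per mutation the number of perturbed genes `x` is 0 with probability
#' `dee_pi0`, exactly 1 with probability `dee_pi1`, and otherwise
#' `round(1 + rgamma(shape, scale))` (minimum 1). Single-target mutations
#' are candidate cis mutations: with probability `cis_fraction` the
#' mutation is placed within 100 bp of its target gene. Multi-target
#' mutations are trans-acting: their targets are drawn from one synthetic
#' co-expression module, mimicking a perturbed regulator whose downstream
#' genes are co-regulated. Genes overlapped by a structural variant gain
#' an effect with probability `sv_effect_prob`.
#'
#' @param cfg a [sim_config()].
#' @param annotation from [generate_annotation()].
#' @return an object of class `ma_truth`: list with `config`, `lines`
#'   (line_id, strain, generations, n_mutations, fitness_rel),
#'   `mutations` (line_id, mut_id, chrom, pos, mut_type, x, cis),
#'   `targets` (line_id, mut_id, gene_id, effect_log2), `effects`
#'   (line_id, gene_id, effect_log2 summed over mutations and SVs),
#'   `svs`, and `modules` (gene_id, module).
#' @export
generate_truth <- function(cfg, annotation) {
  validate_sim_config(unclass(cfg))
  if (nrow(annotation) == 0L) stopf("annotation is empty")
  set.seed(child_seed(cfg$seed, 2L))
  n_genes <- nrow(annotation)
  chrom_len <- attr(annotation, "chrom_lengths")
  if (is.null(chrom_len)) {
    chrom_len <- tapply(annotation$end, annotation$chrom, max)
  }
  chroms <- names(chrom_len)
  modules <- data.frame(
    gene_id = annotation$gene_id,
    module = sample(rep_len(seq_len(max(1L, cfg$n_modules)), n_genes)),
    stringsAsFactors = FALSE
  )
  module_genes <- split(modules$gene_id, modules$module)

  lines <- list(); muts <- list(); targets <- list(); svs <- list()
  sv_types <- c("insertion", "deletion", "duplication",
                "excision", "inversion", "translocation")
  sv_wt <- c(125, 14, 41, 18, 11, 29) / 238
  sv_len_mu <- c(insertion = 263, deletion = 12405, duplication = 16227,
                 excision = 9, inversion = 1504, translocation = 10)

  random_pos <- function(n) {
    ci <- sample(seq_along(chroms), n, replace = TRUE,
                 prob = chrom_len / sum(chrom_len))
    data.frame(chrom = chroms[ci],
               pos = floor(stats::runif(n) * chrom_len[ci]),
               stringsAsFactors = FALSE)
  }

  draw_x <- function(n) {
    if (n == 0L) return(integer(0))
    u <- stats::runif(n)
    x <- integer(n)
    nonnull <- u >= cfg$dee_pi0
    one_spike <- nonnull & u < cfg$dee_pi0 + cfg$dee_pi1
    gam <- nonnull & !one_spike
    x[one_spike] <- 1L
    if (any(gam)) {
      g <- stats::rgamma(sum(gam), shape = cfg$dee_shape, scale = cfg$dee_scale)
      x[gam] <- pmax(1L, as.integer(round(1 + g)))
    }
    x
  }

  for (s in seq_len(cfg$n_strains)) {
    for (l in seq_len(cfg$lines_per_strain[s])) {
      line_id <- sprintf("S%d_L%02d", s, l)
      gen <- round(stats::runif(1, cfg$generations_range[1], cfg$generations_range[2]))
      m <- stats::rpois(1, cfg$mean_mutations_per_line[s])
      mut <- if (m > 0) {
        mm <- random_pos(m)
        mm$line_id <- line_id
        mm$mut_id <- sprintf("%s_m%04d", line_id, seq_len(m))
        mm$mut_type <- sample(c("SNM", "indel"), m, replace = TRUE, prob = c(0.9, 0.1))
        mm$x <- draw_x(m)
        mm$cis <- FALSE
        mm
      } else NULL
      tg <- NULL
      if (!is.null(mut) && any(mut$x > 0)) {
        # single-target ("cis-candidate") mutations, vectorized
        ones <- which(mut$x == 1L)
        tg_mut <- character(0); tg_gene <- character(0)
        if (length(ones)) {
          gene_i <- sample.int(n_genes, length(ones), replace = TRUE)
          is_cis <- stats::runif(length(ones)) < cfg$cis_fraction
          if (any(is_cis)) {
            gi <- gene_i[is_cis]
            lo <- pmax(0, annotation$start[gi] - 100)
            hi <- pmin(chrom_len[annotation$chrom[gi]], annotation$end[gi] + 100)
            mut$chrom[ones[is_cis]] <- annotation$chrom[gi]
            mut$pos[ones[is_cis]] <- floor(lo + stats::runif(length(gi)) * (hi - lo))
            mut$cis[ones[is_cis]] <- TRUE
          }
          tg_mut <- mut$mut_id[ones]
          tg_gene <- annotation$gene_id[gene_i]
        }
        # multi-target ("trans") mutations draw from one module each
        multi <- which(mut$x >= 2L)
        if (length(multi)) {
          mods <- sample.int(length(module_genes), length(multi), replace = TRUE)
          gl <- lapply(seq_along(multi), function(k) {
            pool <- module_genes[[mods[k]]]
            sample(pool, min(mut$x[multi[k]], length(pool)))
          })
          tg_mut <- c(tg_mut, rep(mut$mut_id[multi], lengths(gl)))
          tg_gene <- c(tg_gene, unlist(gl, use.names = FALSE))
        }
        tg <- data.frame(
          line_id = line_id, mut_id = tg_mut, gene_id = tg_gene,
          effect_log2 = stats::rnorm(length(tg_gene), 0, cfg$effect_sd_log2),
          stringsAsFactors = FALSE
        )
      }
      # structural variants
      nsv <- stats::rpois(1, cfg$sv_per_line)
      sv <- NULL
      if (nsv > 0) {
        pos <- random_pos(nsv)
        type <- sample(sv_types, nsv, replace = TRUE, prob = sv_wt)
        len <- pmax(1, round(stats::rlnorm(nsv, log(sv_len_mu[type]), 0.8)))
        sv <- data.frame(
          chrom = pos$chrom,
          start = pos$pos,
          end = pmin(pos$pos + len, chrom_len[pos$chrom]),
          sv_type = type, line_id = line_id,
          stringsAsFactors = FALSE
        )
        hit <- overlapped_genes(sv, annotation)
        if (length(hit)) {
          affected <- hit[stats::runif(length(hit)) < cfg$sv_effect_prob]
          if (length(affected)) {
            tg <- rbind(tg, data.frame(
              line_id = line_id, mut_id = NA_character_, gene_id = affected,
              effect_log2 = stats::rnorm(length(affected), 0, cfg$effect_sd_log2),
              stringsAsFactors = FALSE
            ))
          }
        }
      }
      n_affected <- length(unique(tg$gene_id))
      fit <- 1 + cfg$fitness_slope * n_affected +
        stats::rnorm(1, 0, cfg$fitness_noise_sd)
      lines[[line_id]] <- data.frame(
        line_id = line_id, strain = sprintf("S%d", s), generations = gen,
        n_mutations = m, fitness_rel = fit, stringsAsFactors = FALSE
      )
      muts[[line_id]] <- mut
      targets[[line_id]] <- tg
      svs[[line_id]] <- sv
    }
  }
  lines <- do.call(rbind, lines)
  rownames(lines) <- NULL
  bind <- function(x) {
    x <- Filter(Negate(is.null), x)
    if (!length(x)) return(NULL)
    out <- do.call(rbind, x); rownames(out) <- NULL; out
  }
  mutations <- bind(muts)
  target_tab <- bind(targets)
  effects <- if (!is.null(target_tab)) {
    agg <- stats::aggregate(effect_log2 ~ line_id + gene_id, target_tab, sum)
    agg[order(agg$line_id, agg$gene_id), ]
  } else {
    data.frame(line_id = character(0), gene_id = character(0),
               effect_log2 = numeric(0))
  }
  rownames(effects) <- NULL
  truth <- list(config = cfg, lines = lines,
                mutations = mutations, targets = target_tab,
                effects = effects, svs = bind(svs), modules = modules)
  class(truth) <- "ma_truth"
  truth
}

# gene_ids whose span intersects any SV interval by >= 1 bp
overlapped_genes <- function(svs, annotation) {
  if (is.null(svs) || nrow(svs) == 0L) return(character(0))
  gr_sv <- GenomicRanges::GRanges(svs$chrom,
    IRanges::IRanges(start = svs$start + 1, end = pmax(svs$end, svs$start + 1)))
  gr_gene <- GenomicRanges::GRanges(annotation$chrom,
    IRanges::IRanges(start = annotation$start + 1, end = annotation$end))
  hits <- GenomicRanges::findOverlaps(gr_gene, gr_sv)
  unique(annotation$gene_id[S4Vectors::queryHits(hits)])
}

#' @export
print.ma_truth <- function(x, ...) {
  cat("Synthetic MA experiment truth\n")
  cat(sprintf("  %d lines, %d mutations, %d perturbed gene effects, %d SVs\n",
              nrow(x$lines),
              if (is.null(x$mutations)) 0L else nrow(x$mutations),
              nrow(x$effects),
              if (is.null(x$svs)) 0L else nrow(x$svs)))
  invisible(x)
}
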