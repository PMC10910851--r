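#' Generate a toy genome annotation
#'
#' Lays out `cfg$n_genes` non-overlapping gene models across the
#' configured chromosomes. Each model is a contiguous interval (no
#' introns) with a 5' and 3' UTR at the strand-appropriate ends; the
#' exonic length is the full gene span. Coordinates are 0-based
#' half-open; the GFF3 writer converts at the boundary.
#'
#' @param cfg a [sim_config()].
#' @return a `data.frame` of class `ma_annotation` with one row per gene:
#'   `gene_id`, `chrom`, `start`, `end`, `strand`, `utr5_start`,
#'   `utr5_end`, `utr3_start`, `utr3_end`, `exonic_length`.
#' @export
generate_annotation <- function(cfg) {
  validate_sim_config(unclass(cfg))
  cols <- c("gene_id", "chrom", "start", "end", "strand",
            "utr5_start", "utr5_end", "utr3_start", "utr3_end",
            "exonic_length")
  if (cfg$n_genes == 0L) {
    ann <- as.data.frame(stats::setNames(rep(list(character(0)), length(cols)), cols))
    ann$start <- ann$end <- ann$utr5_start <- ann$utr5_end <-
      ann$utr3_start <- ann$utr3_end <- ann$exonic_length <- numeric(0)
    class(ann) <- c("ma_annotation", "data.frame")
    attr(ann, "chrom_lengths") <- cfg$chrom_lengths
    return(ann)
  }
  set.seed(child_seed(cfg$seed, 1L))
  n_chrom <- length(cfg$chrom_lengths)
  chrom_names <- sprintf("chr%02d", seq_len(n_chrom))
  # apportion genes to chromosomes proportional to length
  alloc <- floor(cfg$n_genes * cfg$chrom_lengths / sum(cfg$chrom_lengths))
  rem <- cfg$n_genes - sum(alloc)
  if (rem > 0) alloc[order(-cfg$chrom_lengths)[seq_len(rem)]] <-
    alloc[order(-cfg$chrom_lengths)[seq_len(rem)]] + 1
  rows <- vector("list", n_chrom)
  gid0 <- 0L
  for (ci in seq_len(n_chrom)) {
    ng <- alloc[ci]
    if (ng == 0) next
    len <- stats::rlnorm(ng, log(1500), 0.5)
    utr5 <- pmax(30, round(stats::rlnorm(ng, log(150), 0.4)))
    utr3 <- pmax(30, round(stats::rlnorm(ng, log(250), 0.4)))
    glen <- round(pmax(len, utr5 + utr3 + 100))
    total <- sum(glen)
    L <- cfg$chrom_lengths[ci]
    if (total > 0.95 * L)
      stopf("cannot pack %d genes (%.0f bp of models) into chromosome of %.0f bp",
            ng, total, L)
    free <- L - total
    gaps <- diff(c(0, sort(stats::runif(ng, 0, free))))
    start <- cumsum(gaps) + cumsum(c(0, glen[-ng]))
    start <- round(start)
    end <- start + glen
    strand <- sample(c("+", "-"), ng, replace = TRUE)
    # 5' UTR sits at the transcription start: left flank on "+", right on "-"
    u5s <- ifelse(strand == "+", start, end - utr5)
    u5e <- ifelse(strand == "+", start + utr5, end)
    u3s <- ifelse(strand == "+", end - utr3, start)
    u3e <- ifelse(strand == "+", end, start + utr3)
    rows[[ci]] <- data.frame(
      gene_id = sprintf("g%05d", gid0 + seq_len(ng)),
      chrom = chrom_names[ci],
      start = start, end = end, strand = strand,
      utr5_start = u5s, utr5_end = u5e,
      utr3_start = u3s, utr3_end = u3e,
      exonic_length = glen,
      stringsAsFactors = FALSE
    )
    gid0 <- gid0 + ng
  }
  ann <- do.call(rbind, rows)
  rownames(ann) <- NULL
  class(ann) <- c("ma_annotation", "data.frame")
  attr(ann, "chrom_lengths") <- stats::setNames(cfg$chrom_lengths, chrom_names)
  ann
}

#' Write / read a toy annotation as GFF3
#'
#' Conversion to the 1-based inclusive GFF3 convention happens here;
#' everything inside the package stays 0-based half-open.
#'
#' @param ann an annotation from [generate_annotation()].
#' @param path output (input) file path.
#' @return `write_annotation_gff3` returns `path` invisibly;
#'   `read_annotation_gff3` returns an `ma_annotation`.
#' @export
write_annotation_gff3 <- function(ann, path) {
  mk <- function(type, s, e) GenomicRanges::GRanges(
    seqnames = ann$chrom,
    ranges = IRanges::IRanges(start = s + 1, end = e),
    strand = ann$strand, type = type, ID = ann$gene_id
  )
  gr <- c(mk("gene", ann$start, ann$end),
          mk("five_prime_UTR", ann$utr5_start, ann$utr5_end),
          mk("three_prime_UTR", ann$utr3_start, ann$utr3_end))
  gr <- sort(gr)
  cl <- attr(ann, "chrom_lengths")
  if (!is.null(cl) && !is.null(names(cl))) {
    GenomeInfoDb::seqlevels(gr) <- names(cl)
    GenomeInfoDb::seqlengths(gr) <- cl
  }
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' @rdname write_annotation_gff3
#' @export
read_annotation_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr)
  genes <- df[df$type == "gene", ]
  pick <- function(type, col) {
    part <- df[df$type == type, c("ID", col)]
    part[[col]][match(genes$ID, part$ID)]
  }
  ann <- data.frame(
    gene_id = genes$ID,
    chrom = as.character(genes$seqnames),
    start = genes$start - 1, end = genes$end,
    strand = as.character(genes$strand),
    utr5_start = pick("five_prime_UTR", "start") - 1,
    utr5_end = pick("five_prime_UTR", "end"),
    utr3_start = pick("three_prime_UTR", "start") - 1,
    utr3_end = pick("three_prime_UTR", "end"),
    exonic_length = genes$end - genes$start + 1,
    stringsAsFactors = FALSE
  )
  ann <- ann[order(ann$gene_id), ]
  rownames(ann) <- NULL
  sl <- GenomeInfoDb::seqlengths(gr)
  class(ann) <- c("ma_annotation", "data.frame")
  attr(ann, "chrom_lengths") <- if (all(!is.na(sl))) sl else NULL
  ann
}
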