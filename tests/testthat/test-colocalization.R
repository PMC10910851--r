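# a tiny hand-built annotation: three genes on one chromosome
toy_annotation <- function() {
  ann <- data.frame(
    gene_id = c("gA", "gB", "gC"),
    chrom = "chr01",
    start = c(1000, 5000, 9000), end = c(2000, 6000, 10000),
    strand = c("+", "-", "+"),
    utr5_start = c(1000, 5800, 9000), utr5_end = c(1200, 6000, 9150),
    utr3_start = c(1750, 5000, 9700), utr3_end = c(2000, 5300, 10000),
    exonic_length = c(1000, 1000, 1000), stringsAsFactors = FALSE)
  class(ann) <- c("ma_annotation", "data.frame")
  attr(ann, "chrom_lengths") <- c(chr01 = 20000)
  ann
}

test_that("nearest mutation distances follow the gene-body and flank rules", {
  ann <- toy_annotation()
  mut <- data.frame(chrom = "chr01", pos = c(1900, 2150))
  # mutation inside gA's 3' UTR -> 1
  expect_equal(unname(nearest_mutation_distance("gA", mut[1, ], ann)), 1)
  # gene [1000,2000), mutation at 2150 -> 150 (half-open arithmetic)
  expect_equal(unname(nearest_mutation_distance("gA", mut[2, ], ann)), 150)
  # per-DEG minimum over all mutations
  expect_equal(unname(nearest_mutation_distance("gA", mut, ann)), 1)
  expect_error(nearest_mutation_distance("gZ", mut, ann), "gZ")
})

test_that("distances match an exhaustive all-pairs scan on random toys", {
  set.seed(21)
  cfg <- sim_config(n_genes = 30, chrom_lengths = 2e5, seed = 6,
                    lines_per_strain = c(1, 1))
  ann <- generate_annotation(cfg)
  mut <- data.frame(chrom = "chr01", pos = sort(sample.int(2e5, 40)))
  got <- nearest_mutation_distance(ann$gene_id, mut, ann)
  for (i in seq_len(nrow(ann))) {
    ds <- vapply(mut$pos, function(p) {
      if (p >= ann$start[i] && p < ann$end[i]) 1
      else min(abs(ann$start[i] - p), abs(p - ann$end[i]))
    }, numeric(1))
    expect_equal(unname(got[i]), min(ds))
  }
})

test_that("distances are invariant under coordinate translation", {
  ann <- toy_annotation()
  mut <- data.frame(chrom = "chr01", pos = c(800, 2150, 7000))
  d1 <- nearest_mutation_distance(ann$gene_id, mut, ann)
  shift <- 500
  ann2 <- ann
  for (col in c("start", "end", "utr5_start", "utr5_end",
                "utr3_start", "utr3_end")) ann2[[col]] <- ann2[[col]] + shift
  attr(ann2, "chrom_lengths") <- c(chr01 = 20500)
  mut2 <- data.frame(chrom = "chr01", pos = mut$pos + shift)
  expect_equal(nearest_mutation_distance(ann2$gene_id, mut2, ann2), d1)
})

test_that("cis enrichment test matches exhaustive enumeration on a toy case", {
  ann <- toy_annotation()
  # one mutation adjacent to gA only
  mut <- data.frame(chrom = "chr01", pos = 2050)
  res <- cis_enrichment_test("gA", mut, ann, window = 100, n_perm = 4000,
                             seed = 3)
  expect_equal(res$observed, 1)
  # exhaustive null over single-gene draws: P(draw gA) = 1/3
  expect_lt(abs(res$p - 1 / 3), 0.03)
  # saturated case: every gene is a DEG -> p = 1
  res2 <- cis_enrichment_test(c("gA", "gB", "gC"), mut, ann, n_perm = 200,
                              seed = 4)
  expect_equal(res2$p, 1)
  expect_error(cis_enrichment_test(character(0), mut, ann), "DEG")
})

test_that("permutation p-values respect the add-one convention bounds", {
  ann <- toy_annotation()
  mut <- data.frame(chrom = "chr01", pos = 2050)
  for (s in 1:5) {
    r <- cis_enrichment_test("gA", mut, ann, n_perm = 50, seed = s)
    expect_gte(r$p, 1 / 51)
    expect_lte(r$p, 1)
  }
})

test_that("UTR enrichment reduces to bp bookkeeping", {
  ann <- toy_annotation()
  # all intragenic mutations inside UTRs; UTR fraction of gene models:
  # (200+250+200+300+150+300)/3000
  mut <- data.frame(chrom = "chr01", pos = c(1100, 1800, 5100))
  ue <- utr_enrichment(mut, ann)
  utr_bp <- (1200 - 1000) + (2000 - 1750) + (6000 - 5800) + (5300 - 5000) +
    (9150 - 9000) + (10000 - 9700)
  expect_equal(ue$fold, 1 / (utr_bp / 3000))
  expect_equal(ue$n_intragenic, 3L)
  expect_equal(ue$n_utr, 3L)
  # genome denominator flag
  ue2 <- utr_enrichment(mut, ann, denominator = "genome")
  expect_equal(ue2$fold, 1 / (utr_bp / 20000))
})

test_that("uniform mutations show no UTR enrichment", {
  cfg <- sim_config(n_genes = 100, chrom_lengths = 1e6, seed = 8,
                    lines_per_strain = c(1, 1))
  ann <- generate_annotation(cfg)
  set.seed(9)
  mut <- data.frame(chrom = "chr01", pos = sample.int(1e6, 1e4))
  ue <- utr_enrichment(mut, ann)
  expect_lt(abs(ue$fold - 1), 0.15)
})

test_that("SV-DEG overlap matches exhaustive enumeration and set semantics", {
  ann <- toy_annotation()
  ann4 <- rbind(ann, data.frame(gene_id = "gD", chrom = "chr01",
                                start = 12000, end = 13000, strand = "+",
                                utr5_start = 12000, utr5_end = 12100,
                                utr3_start = 12900, utr3_end = 13000,
                                exonic_length = 1000))
  class(ann4) <- c("ma_annotation", "data.frame")
  attr(ann4, "chrom_lengths") <- c(chr01 = 20000)
  sv <- data.frame(chrom = "chr01", start = 1500, end = 1600,
                   sv_type = "deletion", line_id = "L1")
  res <- sv_deg_overlap_test(sv, "gA", ann4, n_perm = 4000, seed = 5)
  expect_equal(res$proportion, 1)
  # exhaustive single-DEG null: only 1 of 4 genes overlaps the SV
  expect_lt(abs(res$p - 1 / 4), 0.03)
  # duplicated SV records do not change the statistic
  res2 <- sv_deg_overlap_test(rbind(sv, sv), "gA", ann4, n_perm = 4000,
                              seed = 5)
  expect_equal(res2$proportion, res$proportion)
  expect_equal(res2$p, res$p)
  # no SVs
  res0 <- sv_deg_overlap_test(sv[0, ], "gA", ann4, n_perm = 100, seed = 1)
  expect_equal(res0$proportion, 0)
  expect_equal(res0$p, 1)
  expect_error(sv_deg_overlap_test(
    data.frame(chrom = "chr01", start = 10, end = 5, sv_type = "x",
               line_id = "L"), "gA", ann4), "malformed")
})

test_that("planted cis signal is detected", {
  cfg <- sim_config(n_strains = 1, lines_per_strain = 4, n_genes = 300,
                    chrom_lengths = 2e6, mean_mutations_per_line = 40,
                    cis_fraction = 0.9, sv_per_line = 0, seed = 14)
  ann <- generate_annotation(cfg)
  tr <- generate_truth(cfg, ann)
  hits <- 0
  for (l in tr$lines$line_id) {
    mu <- tr$mutations[tr$mutations$line_id == l, ]
    degs <- unique(tr$effects$gene_id[tr$effects$line_id == l])
    r <- cis_enrichment_test(degs, mu, ann, n_perm = 500, seed = 21)
    hits <- hits + (r$p < 0.05)
  }
  expect_gte(hits, 3)
})
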