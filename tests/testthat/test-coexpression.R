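tom_oracle <- function(A) {
  n <- nrow(A)
  k <- rowSums(A)
  out <- matrix(1, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    num <- sum(A[i, -c(i, j)] * A[-c(i, j), j]) + A[i, j]
    out[i, j] <- num / (min(k[i], k[j]) + 1 - A[i, j])
  }
  out
}

test_that("perfectly correlated genes give unit adjacency and TOM", {
  x <- seq_len(8)
  expr <- rbind(a = x, b = 2 * x + 3)
  net <- build_network(expr, beta = 2)
  expect_equal(net$adjacency["a", "b"], 1)
  expect_equal(net$tom["a", "b"], 1)
})

test_that("TOM matches a symbol-by-symbol evaluation of the formula", {
  set.seed(41)
  expr <- matrix(rnorm(6 * 20), 6, 20,
                 dimnames = list(paste0("g", 1:6), NULL))
  net <- build_network(expr, beta = 2)
  expect_equal(net$tom, tom_oracle(net$adjacency), ignore_attr = TRUE,
               tolerance = 1e-12)
  # TOM is symmetric, unit diagonal, entries in [0, 1]
  expect_equal(net$tom, t(net$tom))
  expect_equal(unname(diag(net$tom)), rep(1, 6))
  expect_true(all(net$tom >= 0 & net$tom <= 1))
  expect_true(all(net$adjacency >= 0 & net$adjacency <= 1))
})

test_that("gene order permutation permutes outputs consistently", {
  sm <- simulate_module_expression(30, 3, 16, seed = 5)
  net1 <- build_network(sm$expr, n_clusters = 3)
  perm <- sample(nrow(sm$expr))
  net2 <- build_network(sm$expr[perm, ], n_clusters = 3)
  g <- rownames(sm$expr)
  expect_equal(net2$adjacency[g, g], net1$adjacency[g, g])
  expect_equal(net2$tom[g, g], net1$tom[g, g])
  m1 <- net1$modules[match(g, net1$modules$gene_id), ]
  m2 <- net2$modules[match(g, net2$modules$gene_id), ]
  expect_equal(m1$k_total, m2$k_total)
  expect_equal(m1$k_within, m2$k_within)
  # same partition up to module relabeling
  expect_equal(length(unique(paste(m1$module, m2$module))),
               length(unique(m1$module)))
})

test_that("constant genes are dropped with a warning", {
  expr <- rbind(a = rnorm(10), b = rnorm(10), c = rep(2, 10), d = rnorm(10))
  expect_warning(net <- build_network(expr), "constant")
  expect_false("c" %in% net$genes)
})

test_that("modules recover planted blocks; merging respects the threshold", {
  sm <- simulate_module_expression(90, 3, 30, cor_within = 0.9,
                                   cor_between = 0.05, seed = 6)
  net <- build_network(sm$expr, n_clusters = 9, merge_cor = 0.75)
  # merging never increases the module count
  expect_lte(net$n_modules, 9)
  tab <- table(net$modules$module, sm$module)
  purity <- mean(apply(tab, 2, max) / colSums(tab))
  expect_gt(purity, 0.9)
  # hub counts: ceil(5% of module size)
  sizes <- table(net$modules$module)
  hubs <- table(net$modules$module[net$modules$is_hub])
  for (mo in names(sizes)) {
    expect_equal(unname(hubs[mo]), ceiling(0.05 * sizes[[mo]]),
                 ignore_attr = TRUE)
  }
})

test_that("path distances equal inverse correlations and brute-force search", {
  # two genes joined by one edge of |cor| 0.5 -> distance 2
  set.seed(7)
  t1 <- rnorm(12)
  expr <- rbind(a = t1, b = 0.5 / sqrt(1 - 0.25) * t1 +
                  rnorm(12) * sqrt(1 - 0.25 / (1 - 0.25)))
  # direct construction is easier: force the sample correlation
  suppressWarnings({
    b <- t1 * 0.5 + rnorm(12)
  })
  expr <- rbind(a = t1, b = b)
  r <- cor(t1, b)
  net <- build_network(expr, cor_floor = 0.05)
  d <- deg_path_distances(net, c("a", "b"))
  expect_equal(d$distance, 1 / abs(r), tolerance = 1e-10)
  # 6-node brute force: enumerate all simple paths
  sm <- simulate_module_expression(6, 2, 15, seed = 8)
  net6 <- build_network(sm$expr, cor_floor = 0.1)
  W <- abs(net6$cor)
  W[W < 0.1] <- 0
  len <- 1 / W
  genes <- rownames(sm$expr)
  paths_min <- function(i, j) {
    best <- Inf
    perms <- function(cur, rest, acc) {
      if (cur == j) { best <<- min(best, acc); return(invisible()) }
      for (k in rest) {
        if (is.finite(len[cur, k])) perms(k, setdiff(rest, k), acc + len[cur, k])
      }
    }
    perms(i, setdiff(seq_along(genes), i), 0)
    best
  }
  D <- deg_path_distances(net6, genes)
  for (row in seq_len(nrow(D))) {
    i <- match(D$gene_a[row], genes); j <- match(D$gene_b[row], genes)
    expect_equal(D$distance[row], paths_min(i, j), tolerance = 1e-10)
  }
})

test_that("adding an edge never lengthens a shortest path", {
  sm <- simulate_module_expression(12, 3, 15, seed = 9)
  net <- build_network(sm$expr, cor_floor = 0.3)
  netd <- build_network(sm$expr, cor_floor = 0.15)   # superset of edges
  genes <- rownames(sm$expr)
  d1 <- deg_path_distances(net, genes)
  d2 <- deg_path_distances(netd, genes)
  key <- function(d) paste(d$gene_a, d$gene_b)
  common <- intersect(key(d1), key(d2))
  expect_true(all(d2$distance[match(common, key(d2))] <=
                    d1$distance[match(common, key(d1))] + 1e-12))
  # triangle inequality on sampled triples
  D <- igraph::distances(net$graph)
  set.seed(10)
  for (t in 1:30) {
    ijk <- sample(nrow(D), 3)
    a <- D[ijk[1], ijk[2]]; b <- D[ijk[2], ijk[3]]; cc <- D[ijk[1], ijk[3]]
    if (is.finite(a) && is.finite(b)) expect_lte(cc, a + b + 1e-12)
  }
})

test_that("clustering test flags module DEGs but not random ones", {
  sm <- simulate_module_expression(120, 6, 24, cor_within = 0.9,
                                   cor_between = 0.1, seed = 11)
  net <- build_network(sm$expr, n_clusters = 8)
  set.seed(12)
  expr_lvl <- setNames(rexp(120, 0.1), rownames(sm$expr))
  deg_mod <- names(sm$module)[sm$module == 3][1:12]
  r1 <- deg_clustering_test(net, deg_mod, expr_lvl, n_perm = 300, seed = 13)
  expect_lt(r1$p, 0.05)
  # single DEG: undefined sentinel
  r0 <- deg_clustering_test(net, deg_mod[1], expr_lvl, n_perm = 50, seed = 1)
  expect_true(is.na(r0$p))
  expect_equal(r0$n_pairs, 0L)
})

test_that("connectivity regression reproduces closed-form OLS", {
  set.seed(14)
  x <- setNames(runif(30, 1, 10), paste0("g", 1:30))
  # deterministic line: R^2 = 1
  y1 <- setNames(0.01 * x, names(x))
  r1 <- suppressWarnings(connectivity_vs_change(x, y1))
  expect_equal(r1$r_squared, 1)
  expect_equal(r1$slope, 0.01, tolerance = 1e-12)
  # normal-equations oracle on a small sample
  xs <- setNames(c(1, 2, 4, 7, 9, 10, 12, 15, 18, 20), paste0("h", 1:10))
  ys <- setNames(c(2.1, 2.0, 3.5, 3.1, 5.0, 4.2, 6.1, 5.9, 7.2, 8.0),
                 names(xs))
  r2 <- connectivity_vs_change(xs, ys)
  X <- cbind(1, unname(xs))
  beta <- solve(t(X) %*% X, t(X) %*% unname(ys))
  expect_equal(r2$slope, beta[2], tolerance = 1e-10)
  expect_error(connectivity_vs_change(x[1:5], y1[1:5]), "10")
})
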