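#' Build a soft-threshold co-expression network
#'
#' From an expression matrix (genes x observations, e.g. a time
#' course), computes the unsigned soft-threshold adjacency
#' \eqn{a_{ij} = |cor(i,j)|^\beta}, the topological overlap matrix
#' \deqn{TOM_{ij} = \frac{\sum_u a_{iu} a_{uj} + a_{ij}}
#'   {\min(k_i, k_j) + 1 - a_{ij}},}
#' clusters genes by average-linkage hierarchical clustering on
#' \eqn{1 - TOM}, cuts the dendrogram into `n_clusters` modules, and
#' iteratively merges module pairs whose eigengenes (first principal
#' component of the module's standardized expression) correlate at or
#' above `merge_cor`. Intramodular and total connectivity are adjacency
#' row sums; hub genes are the top 5% of intramodular connectivity per
#' module. For path queries, edges with \eqn{|cor|} at or above
#' `cor_floor` get length \eqn{1/|cor|}.
#'
#' @param expr numeric matrix, genes x observations (>= 4 observations).
#' @param beta soft-threshold power.
#' @param n_clusters modules to cut before merging (default: a size
#'   heuristic, roughly one module per 25 genes, between 2 and 33).
#' @param merge_cor eigengene correlation at which modules merge.
#' @param cor_floor minimum |correlation| for a path edge.
#' @return an object of class `coexpr_network`: `genes`, `cor`,
#'   `adjacency`, `tom`, `modules` (gene_id, module, k_total, k_within,
#'   is_hub), `graph` (igraph, edge weight = 1/|cor|), `beta`,
#'   `cor_floor`, `n_modules`.
#' @export
build_network <- function(expr, beta = 2, n_clusters = NULL,
                          merge_cor = 0.75, cor_floor = 0.1) {
  expr <- as.matrix(expr)
  if (ncol(expr) < 4) stopf("need >= 4 observations per gene")
  sds <- apply(expr, 1, stats::sd)
  if (any(sds == 0)) {
    warning(sprintf("dropping %d constant-expression gene(s)", sum(sds == 0)))
    expr <- expr[sds > 0, , drop = FALSE]
  }
  n <- nrow(expr)
  if (n < 2) stopf("need >= 2 variable genes")
  genes <- rownames(expr) %||% sprintf("g%04d", seq_len(n))
  rownames(expr) <- genes
  cr <- stats::cor(t(expr))
  A <- abs(cr)^beta
  diag(A) <- 0
  k <- rowSums(A)
  num <- A %*% A + A
  den <- outer(k, k, pmin) + 1 - A
  tom <- num / den
  diag(tom) <- 1
  tom <- pmin(pmax((tom + t(tom)) / 2, 0), 1)
  hc <- stats::hclust(stats::as.dist(1 - tom), method = "average")
  if (is.null(n_clusters)) n_clusters <- max(2L, min(33L, floor(n / 25)))
  module <- stats::cutree(hc, k = min(n_clusters, n))
  module <- merge_modules(expr, module, merge_cor)
  k_within <- vapply(seq_len(n), function(i) sum(A[i, module == module[i]]),
                     numeric(1))
  modules <- data.frame(gene_id = genes, module = module,
                        k_total = k, k_within = k_within,
                        is_hub = FALSE, stringsAsFactors = FALSE)
  for (mo in unique(module)) {
    ix <- which(module == mo)
    n_hub <- ceiling(0.05 * length(ix))
    top <- ix[order(-k_within[ix])[seq_len(n_hub)]]
    modules$is_hub[top] <- TRUE
  }
  g <- graph_from_cor(cr, cor_floor)
  out <- list(genes = genes, cor = cr, adjacency = A, tom = tom,
              modules = modules, graph = g, beta = beta,
              cor_floor = cor_floor, n_modules = length(unique(module)))
  class(out) <- "coexpr_network"
  out
}

module_eigengenes <- function(expr, module) {
  vapply(sort(unique(module)), function(mo) {
    sub <- scale(t(expr[module == mo, , drop = FALSE]))
    if (ncol(sub) == 1) return(drop(sub))
    sv <- svd(sub, nu = 1, nv = 0)
    e <- sv$u[, 1]
    # orient so the eigengene correlates positively with mean expression
    if (stats::cor(e, rowMeans(sub)) < 0) e <- -e
    e
  }, numeric(ncol(expr)))
}

merge_modules <- function(expr, module, merge_cor) {
  repeat {
    ids <- sort(unique(module))
    if (length(ids) < 2) break
    eg <- module_eigengenes(expr, module)
    colnames(eg) <- ids
    ec <- stats::cor(eg)
    diag(ec) <- -Inf
    mx <- which(ec == max(ec), arr.ind = TRUE)[1, ]
    if (ec[mx[1], mx[2]] < merge_cor) break
    module[module == ids[mx[2]]] <- ids[mx[1]]
  }
  match(module, sort(unique(module)))  # renumber 1..K
}

graph_from_cor <- function(cr, cor_floor) {
  ac <- abs(cr)
  ac[lower.tri(ac, diag = TRUE)] <- 0
  keep <- which(ac >= cor_floor, arr.ind = TRUE)
  g <- igraph::make_empty_graph(n = nrow(cr), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = rownames(cr))
  if (nrow(keep)) {
    g <- igraph::add_edges(g, t(keep))
    g <- igraph::set_edge_attr(g, "weight", value = 1 / ac[keep])
  }
  g
}

#' Shortest-path distances between DEG pairs in the network
#'
#' Edge lengths are inverse absolute correlations; pairs with no
#' connecting path are excluded.
#'
#' @param network a `coexpr_network` (or an igraph with a `weight`
#'   edge attribute and named vertices).
#' @param deg_set gene ids.
#' @return data.frame `gene_a`, `gene_b`, `distance` for connected
#'   pairs.
#' @export
deg_path_distances <- function(network, deg_set) {
  g <- if (inherits(network, "coexpr_network")) network$graph else network
  deg_set <- intersect(unique(deg_set), igraph::V(g)$name)
  if (length(deg_set) < 2)
    return(data.frame(gene_a = character(0), gene_b = character(0),
                      distance = numeric(0)))
  D <- igraph::distances(g, v = deg_set, to = deg_set)
  ut <- which(upper.tri(D), arr.ind = TRUE)
  d <- D[ut]
  ok <- is.finite(d)
  data.frame(gene_a = rownames(D)[ut[ok, 1]],
             gene_b = colnames(D)[ut[ok, 2]],
             distance = d[ok], stringsAsFactors = FALSE)
}

# expression-matched strata: `bins` quantile bins with the top bin
# split further (right-skewed read counts concentrate there)
expression_strata <- function(expr_level, bins = 5, split_top = TRUE) {
  r <- rank(expr_level, ties.method = "first")
  cut_pts <- stats::quantile(r, probs = seq(0, 1, length.out = bins + 1))
  s <- cut(r, breaks = unique(cut_pts), include.lowest = TRUE, labels = FALSE)
  if (split_top && bins >= 2) {
    top <- which(s == max(s))
    if (length(top) >= 4) {
      med <- stats::median(r[top])
      s[top[r[top] > med]] <- max(s) + 1L
    }
  }
  s
}

#' Expression-matched permutation test for DEG network clustering
#'
#' Tests whether a line's DEGs lie closer together in the co-expression
#' network than random gene sets matched on expression level. The
#' statistic is the median pairwise shortest-path length among DEGs.
#' The null draws, per permutation, the same number of genes from each
#' expression stratum (quantile bins of the ancestral expression; the
#' top bin is subdivided) and recomputes the median. Small strata are
#' sampled with replacement and flagged.
#'
#' @param network a `coexpr_network`.
#' @param deg_set DEG gene ids.
#' @param ancestral_expression named per-gene expression levels used
#'   for matching (e.g. ancestral mean FPKM); must cover the network
#'   genes.
#' @param n_perm permutation draws.
#' @param seed integer seed.
#' @param bins base number of expression strata.
#' @return list: `observed_median`, `p` (add-one; fraction of draws
#'   with median <= observed), `significant`, `n_pairs`,
#'   `with_replacement` flag, `n_perm`. When fewer than 2 connected
#'   DEGs exist the test is undefined and `p` is NA.
#' @export
deg_clustering_test <- function(network, deg_set, ancestral_expression,
                                n_perm = 1000, seed = 1L, bins = 5) {
  g <- network$graph
  genes <- igraph::V(g)$name
  expr_level <- ancestral_expression[genes]
  if (anyNA(expr_level)) stopf("ancestral expression missing for network gene(s)")
  deg_set <- intersect(unique(deg_set), genes)
  obs <- deg_path_distances(network, deg_set)
  if (length(deg_set) < 2 || !nrow(obs))
    return(list(observed_median = NA_real_, p = NA_real_, significant = NA,
                n_pairs = nrow(obs), with_replacement = FALSE, n_perm = n_perm))
  obs_med <- stats::median(obs$distance)
  strata <- expression_strata(expr_level, bins = bins)
  deg_strata <- strata[match(deg_set, genes)]
  need <- table(deg_strata)
  pools <- split(seq_along(genes), strata)
  with_repl <- FALSE
  D <- igraph::distances(g)
  set.seed(child_seed(seed, 40L))
  perm_med <- vapply(seq_len(n_perm), function(i) {
    pick <- unlist(lapply(names(need), function(st) {
      pool <- pools[[st]]
      k <- need[[st]]
      if (length(pool) < k) { with_repl <<- TRUE
        sample(pool, k, replace = TRUE)
      } else sample(pool, k)
    }), use.names = FALSE)
    sub <- D[pick, pick]
    d <- sub[upper.tri(sub)]
    d <- d[is.finite(d)]
    if (!length(d)) return(Inf)
    stats::median(d)
  }, numeric(1))
  p <- perm_pvalue(sum(perm_med <= obs_med), n_perm)
  list(observed_median = obs_med, p = p, significant = p < 0.05,
       n_pairs = nrow(obs), with_replacement = with_repl, n_perm = n_perm)
}

#' Regression of expression change on network connectivity
#'
#' Ordinary least squares of the per-gene expression change (median
#' |log2 fold change| across lines) on a connectivity measure, plus a
#' rank-based comparison of the top versus bottom connectivity deciles
#' (Brunner-Munzel).
#'
#' @param connectivity named per-gene connectivity (e.g. `k_within`
#'   from a `coexpr_network`, or degree in a metabolic network).
#' @param change named per-gene median |log2fc|.
#' @return list: `slope`, `r_squared`, `p` (slope test),
#'   `group_comparison` (the [brunner_munzel()] result for bottom vs
#'   top decile), `group_medians`, `n`.
#' @export
connectivity_vs_change <- function(connectivity, change) {
  common <- intersect(names(connectivity), names(change))
  if (length(common) < 10) stopf("fewer than 10 genes joinable")
  x <- as.numeric(connectivity[common])
  y <- as.numeric(change[common])
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  q <- stats::quantile(x, c(0.1, 0.9))
  lo <- y[x <= q[1]]; hi <- y[x >= q[2]]
  bm <- if (length(lo) >= 2 && length(hi) >= 2)
    tryCatch(brunner_munzel(lo, hi), error = function(e) NULL) else NULL
  list(slope = unname(stats::coef(fit)[2]),
       r_squared = sm$r.squared,
       p = unname(sm$coefficients[2, 4]),
       group_comparison = bm,
       group_medians = c(low = stats::median(lo), high = stats::median(hi)),
       n = length(common))
}

#' @export
print.coexpr_network <- function(x, ...) {
  cat(sprintf("Co-expression network: %d genes, %d modules (beta = %g)\n",
              length(x$genes), x$n_modules, x$beta))
  cat(sprintf("  %d hub genes; path edges at |cor| >= %g\n",
              sum(x$modules$is_hub), x$cor_floor))
  invisible(x)
}
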