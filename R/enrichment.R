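#' Hypergeometric functional-category enrichment
#'
#' Upper-tail hypergeometric over-representation test of a query gene set
#' against a collection of categories (e.g. a GMT file read with
#' [read_gmt()]): with population size N, category size K, query size n and
#' overlap k, `p = P(X >= k)` for X hypergeometric. Categories passing the
#' cutoff are returned sorted by p.
#'
#' @param query character vector of genes (must lie in the population).
#' @param categories named list of character vectors (category members).
#' @param universe population of genes; defaults to the union of all
#'   category members.
#' @param p_cutoff report categories with `p < p_cutoff` (default 0.01;
#'   use 1 to keep everything).
#' @return data.frame: category, p_value, N, K, n, k, members (comma-joined
#'   overlap), sorted by p ascending.
#' @export
hypergeom_enrich <- function(query, categories, universe = NULL,
                             p_cutoff = 0.01) {
  if (is.null(universe)) universe <- unique(unlist(categories))
  if (!length(universe)) stop("empty population")
  universe <- unique(universe)
  query <- unique(intersect(query, universe))
  res <- lapply(names(categories), function(nm) {
    members <- unique(intersect(categories[[nm]], universe))
    k <- length(intersect(query, members))
    K <- length(members)
    N <- length(universe)
    n <- length(query)
    p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    data.frame(category = nm, p_value = p, N = N, K = K, n = n, k = k,
               members = paste(sort(intersect(query, members)),
                               collapse = ","),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  res <- res[res$p_value < p_cutoff, , drop = FALSE]
  res <- res[order(res$p_value, res$category), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Filter pathways by measurement coverage
#'
#' Retains pathways for which at least `min_coverage` of member genes have
#' measured data (e.g. are represented on the array). The boundary is
#' inclusive: a 10-gene pathway with 6 measured genes is retained at 0.6.
#'
#' @param pathways list of pathways, each a list with `id` and `nodes`
#'   (as from [generate_pathways()] or [read_pathway_edges()]).
#' @param measured character vector of genes with data.
#' @param min_coverage retention threshold in `[0, 1]`.
#' @return the retained pathways, each with a `coverage` field added.
#' @export
coverage_filter <- function(pathways, measured, min_coverage = 0.6) {
  kept <- lapply(pathways, function(pw) {
    pw$coverage <- mean(pw$nodes %in% measured)
    pw
  })
  kept[vapply(kept, function(pw) pw$coverage >= min_coverage, logical(1))]
}

#' Graph-aware permutation pathway enrichment test
#'
#' Permutation test that rewards pathways whose perturbed genes are close
#' to each other in the pathway graph. The observed statistic is
#' `T = mean_g s_g + mean_(g,h in E) min(s_g, s_h)` -- the average node
#' statistic plus an edge term that is large only when adjacent genes are
#' *both* perturbed (the edge term is 0 for pathways without edges). The
#' null draws `|V|` statistics without replacement from the gene-universe
#' pool and assigns them to node positions at random, recomputing T;
#' `p = (1 + #T* >= T) / (n_perm + 1)` (add-one convention, ties counted
#' conservatively). The null hypothesis is that the gene-level statistics
#' of the pathway's genes are exchangeable with the rest of the universe,
#' i.e. the pathway's growth phenotype is independent of dose.
#'
#' @param pathway list with `nodes` and `edges` (2-column matrix of node
#'   ids; may have zero rows).
#' @param gene_stats named numeric vector of per-gene statistics (e.g.
#'   Kruskal-Wallis H from [kw_statistic()]) over the whole universe.
#' @param n_perm number of permutations (>= 99).
#' @param seed integer seed.
#' @return data.frame: statistic, p_value, n_permutations, n_nodes,
#'   n_edges, members (comma-joined pathway genes with statistics).
#' @export
sepea_test <- function(pathway, gene_stats, n_perm = 1e5L, seed = 1L) {
  stopifnot(n_perm >= 99L, !is.null(names(gene_stats)))
  nodes <- intersect(pathway$nodes, names(gene_stats))
  if (length(nodes) > length(gene_stats))
    stop("pathway larger than statistic universe")
  if (length(nodes) < 2L) stop("pathway needs >=2 measured nodes")
  s <- gene_stats[nodes]
  edges <- pathway$edges
  if (!is.null(edges) && nrow(edges)) {
    keep <- edges[, 1L] %in% nodes & edges[, 2L] %in% nodes
    edges <- edges[keep, , drop = FALSE]
  }
  e1 <- match(edges[, 1L], nodes)
  e2 <- match(edges[, 2L], nodes)
  t_obs <- sepea_statistic(s, e1, e2)
  pool <- unname(gene_stats)
  v <- length(nodes)
  t_null <- withr::with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      ss <- pool[sample.int(length(pool), v)]
      sepea_statistic(ss, e1, e2)
    }, numeric(1))
  })
  p <- (1 + sum(t_null >= t_obs - 1e-12)) / (n_perm + 1)
  data.frame(statistic = t_obs, p_value = p, n_permutations = n_perm,
             n_nodes = v, n_edges = length(e1),
             members = paste(nodes, collapse = ","),
             stringsAsFactors = FALSE)
}

sepea_statistic <- function(s, e1, e2) {
  node_term <- mean(s)
  edge_term <- if (length(e1)) mean(pmin(s[e1], s[e2])) else 0
  node_term + edge_term
}

#' Exhaustive-assignment version of the graph-aware enrichment p-value
#'
#' Enumerates every ordered assignment of universe statistics to the
#' pathway's node positions and computes the exact tail probability of the
#' observed statistic. Only feasible for tiny pathways/universes; serves as
#' the ground truth for the Monte-Carlo test.
#'
#' @inheritParams sepea_test
#' @return exact p-value (proportion of assignments with `T* >= T_obs`).
#' @export
sepea_exact <- function(pathway, gene_stats) {
  nodes <- intersect(pathway$nodes, names(gene_stats))
  s <- gene_stats[nodes]
  edges <- pathway$edges
  if (!is.null(edges) && nrow(edges)) {
    keep <- edges[, 1L] %in% nodes & edges[, 2L] %in% nodes
    edges <- edges[keep, , drop = FALSE]
  }
  e1 <- match(edges[, 1L], nodes)
  e2 <- match(edges[, 2L], nodes)
  t_obs <- sepea_statistic(s, e1, e2)
  pool <- unname(gene_stats)
  v <- length(nodes)
  combs <- utils::combn(length(pool), v)
  perms <- all_permutations(v)
  total <- 0L
  hits <- 0L
  for (ci in seq_len(ncol(combs))) {
    vals <- pool[combs[, ci]]
    for (pi in seq_len(nrow(perms))) {
      tt <- sepea_statistic(vals[perms[pi, ]], e1, e2)
      hits <- hits + (tt >= t_obs - 1e-12)
      total <- total + 1L
    }
  }
  hits / total
}

all_permutations <- function(k) {
  if (k == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(k - 1L)
  do.call(rbind, lapply(seq_len(k), function(i) {
    rest <- setdiff(seq_len(k), i)
    cbind(i, matrix(rest[sub], nrow = nrow(sub)))
  }))
}

#' Hierarchical clustering of pathway p-value profiles
#'
#' Transforms a pathway-by-condition matrix of enrichment p-values to
#' `-log10 p`, computes pairwise distances `1 - Spearman correlation`
#' between pathway profiles, and clusters by average linkage. Missing
#' p-values are imputed as 1 (with a warning); constant profiles have
#' undefined correlation and are placed at the maximum distance 2 (with a
#' warning).
#'
#' @param p_matrix numeric matrix of p-values, rows pathways, columns
#'   conditions; rownames identify pathways.
#' @return list: `neglog10` matrix, `dist` (dist object), `tree` (hclust),
#'   `leaf_order` (pathway ids in dendrogram order).
#' @export
cluster_pathways <- function(p_matrix) {
  stopifnot(is.matrix(p_matrix), nrow(p_matrix) >= 2L)
  if (anyNA(p_matrix)) {
    warning("missing p-values imputed as 1")
    p_matrix[is.na(p_matrix)] <- 1
  }
  x <- -log10(pmax(p_matrix, 1e-300))
  suppressWarnings(cc <- stats::cor(t(x), method = "spearman"))
  if (anyNA(cc)) {
    warning("constant pathway profile(s): distance set to maximum (2)")
    cc[is.na(cc)] <- -1
  }
  diag(cc) <- 1
  d <- stats::as.dist(1 - cc)
  tree <- stats::hclust(d, method = "average")
  list(neglog10 = x, dist = d, tree = tree,
       leaf_order = rownames(p_matrix)[tree$order])
}
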