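#' Upper-tail hypergeometric p-value
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: the chance of drawing at
#' least k annotated genes when n genes are drawn without replacement from a
#' universe of N genes of which K are annotated. Computed in log space via
#' [stats::phyper()], numerically stable for large N. Vectorized over `k`,
#' `K`, `n`.
#'
#' @param k Observed overlap.
#' @param K Annotated-set size within the universe.
#' @param n Query (draw) size.
#' @param N Universe size.
#' @export
hypergeom_pvalue <- function(k, K, n, N) {
  if (any(K > N) || any(n > N)) stopf("K and n must not exceed N")
  if (any(k > pmin(K, n)) || any(k < 0)) stopf("k must lie in [0, min(K, n)]")
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini--Hochberg FDR adjustment
#'
#' Step-up BH with monotonicity enforcement; output order matches input.
#'
#' @param pvalues Numeric vector of p-values in `[0,1]`.
#' @export
bh_adjust <- function(pvalues) {
  stopifnot(all(pvalues >= 0 & pvalues <= 1))
  stats::p.adjust(pvalues, method = "BH")
}

#' Overlap coefficient between two gene sets
#'
#' `|A intersect B| / min(|A|, |B|)`, in `[0,1]`.
#'
#' @param a,b Character vectors.
#' @export
overlap_coefficient <- function(a, b) {
  a <- unique(a); b <- unique(b)
  if (!length(a) || !length(b)) return(0)
  length(intersect(a, b)) / min(length(a), length(b))
}

#' Pathway over-representation analysis
#'
#' One upper-tail hypergeometric test per gene set, after restricting sets to
#' the universe and applying the size filter on the restricted size
#' (`min_size` to `max_size` genes). Query genes outside the universe are
#' logged and dropped. P-values are BH-adjusted across the surviving sets.
#'
#' @param query Character vector of query genes.
#' @param collection Named list of gene sets (e.g. from [read_gmt()]).
#' @param universe Background gene set.
#' @param min_size,max_size Size filter on `|set intersect universe|`
#'   (defaults 3 and 200).
#' @return An enrichment table: `data.frame` with `set`, `k`, `K`, `n`, `N`,
#'   `p`, `fdr` and `overlap` (comma-joined overlap genes), sorted by p then
#'   set name.
#' @export
pathway_ora <- function(query, collection, universe, min_size = 3L,
                        max_size = 200L) {
  stopifnot(is.list(collection), !is.null(names(collection)))
  universe <- unique(as.character(universe))
  if (!length(universe)) stopf("empty universe")
  query <- unique(as.character(query))
  outside <- setdiff(query, universe)
  if (length(outside)) {
    message(sprintf("pathway_ora: %d query genes outside the universe, dropped",
                    length(outside)))
    query <- intersect(query, universe)
  }
  sets <- lapply(collection, function(s) intersect(unique(s), universe))
  sz <- lengths(sets)
  keep <- sz >= min_size & sz <= max_size
  sets <- sets[keep]
  if (!length(sets)) {
    return(data.frame(set = character(), k = integer(), K = integer(),
                      n = integer(), N = integer(), p = numeric(),
                      fdr = numeric(), overlap = character(),
                      stringsAsFactors = FALSE))
  }
  N <- length(universe)
  n <- length(query)
  ov <- lapply(sets, intersect, query)
  k <- lengths(ov)
  K <- lengths(sets)
  p <- hypergeom_pvalue(k, K, n, N)
  tab <- data.frame(set = names(sets), k = as.integer(k), K = as.integer(K),
                    n = n, N = N, p = p, fdr = bh_adjust(p),
                    overlap = vapply(ov, function(g) paste(sort(g), collapse = ","), ""),
                    stringsAsFactors = FALSE)
  tab <- tab[order(tab$p, tab$set), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Meta-pathway clustering via the overlap-coefficient pathway network
#'
#' Eligible pathways (overlap of at least `min_network_genes` query genes and
#' `fdr < fdr_max` in the enrichment table) become nodes of a pathway network
#' with an edge wherever the overlap coefficient of the two gene sets exceeds
#' a threshold. The threshold is chosen from `threshold_grid` as the value
#' maximizing fastgreedy modularity of the resulting (binarized) graph,
#' smallest on ties; meta-pathways are the fastgreedy communities at that
#' threshold.
#'
#' @param enriched Enrichment table from [pathway_ora()].
#' @param collection The gene-set collection the table was computed from.
#' @param min_network_genes Minimum overlap-gene count (default 3).
#' @param fdr_max FDR cut for eligibility (default 0.05).
#' @param threshold_grid Candidate thresholds (default 0.05 to 0.95 by 0.05).
#' @return Object of class `meta_pathways`: list with `pathways`, `edges`
#'   (data.frame a, b, coefficient), `threshold`, `Q`, `clusters` (named
#'   integer vector), `objective` (Q per grid threshold).
#' @export
meta_pathways <- function(enriched, collection, min_network_genes = 3L,
                          fdr_max = 0.05,
                          threshold_grid = seq(0.05, 0.95, by = 0.05)) {
  eligible <- enriched$set[enriched$k >= min_network_genes &
                             enriched$fdr < fdr_max]
  sets <- collection[eligible]
  np <- length(sets)
  if (np < 2) {
    warning("fewer than 2 eligible pathways: single trivial cluster")
    cl <- stats::setNames(rep(1L, np), eligible)
    return(structure(list(pathways = eligible,
                          edges = data.frame(a = character(), b = character(),
                                             coefficient = numeric()),
                          threshold = NA_real_, Q = 0, clusters = cl,
                          objective = NULL),
                     class = "meta_pathways"))
  }
  prs <- utils::combn(np, 2)
  coef <- vapply(seq_len(ncol(prs)), function(ix) {
    overlap_coefficient(sets[[prs[1, ix]]], sets[[prs[2, ix]]])
  }, 0)
  qs <- vapply(threshold_grid, function(th) {
    keep <- coef > th
    if (!any(keep)) return(0)
    g <- igraph::graph_from_data_frame(
      data.frame(a = eligible[prs[1, keep]], b = eligible[prs[2, keep]]),
      directed = FALSE, vertices = data.frame(name = eligible))
    detect_communities(g, "fastgreedy")$Q
  }, 0)
  th <- threshold_grid[order(-qs, threshold_grid)][1]
  keep <- coef > th
  g <- igraph::graph_from_data_frame(
    data.frame(a = eligible[prs[1, keep]], b = eligible[prs[2, keep]]),
    directed = FALSE, vertices = data.frame(name = eligible))
  part <- detect_communities(g, "fastgreedy")
  structure(list(pathways = eligible,
                 edges = data.frame(a = eligible[prs[1, keep]],
                                    b = eligible[prs[2, keep]],
                                    coefficient = coef[keep],
                                    stringsAsFactors = FALSE),
                 threshold = th, Q = part$Q, clusters = part$membership,
                 objective = stats::setNames(qs, threshold_grid)),
            class = "meta_pathways")
}

#' @export
print.meta_pathways <- function(x, ...) {
  cat(sprintf("<meta_pathways> %d pathways, threshold %.2f, Q = %.3f, %d meta-pathways\n",
              length(x$pathways), x$threshold, x$Q,
              length(unique(x$clusters))))
  invisible(x)
}
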