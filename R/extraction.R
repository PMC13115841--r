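#' Candidate top-r subnetworks
#'
#' One candidate per r on the inclusive grid `seq(r_min, r_max, step)`: the
#' top r genes of the deterministic S~ ranking and the subgraph they induce in
#' the interactome.
#'
#' @param result A `diffusion_result`.
#' @param net The `interactome` the diffusion ran on.
#' @param r_min,r_max,step Sweep grid (defaults 50, 500, 10).
#' @return List of `candidate_network` objects (fields `r`, `genes`, `edges`,
#'   scores `NA` until [score_candidate()]).
#' @export
candidate_networks <- function(result, net, r_min = 50L, r_max = 500L,
                               step = 10L) {
  stopifnot(inherits(result, "diffusion_result"), inherits(net, "interactome"))
  if (r_min > r_max) stopf("r_min (%d) > r_max (%d)", r_min, r_max)
  n <- length(result$ranking)
  if (r_max > n) stopf("r_max (%d) exceeds the number of genes (%d)", r_max, n)
  lapply(seq(r_min, r_max, by = step), function(r) {
    genes <- result$ranking[seq_len(r)]
    keep <- net$edges$gene_a %in% genes & net$edges$gene_b %in% genes
    structure(list(r = as.integer(r), genes = genes,
                   edges = net$edges[keep, , drop = FALSE],
                   modularity_Q = NA_real_, n_sig = NA_integer_,
                   p_resampling = NA_real_, p_disease_enrichment = NA_real_,
                   composite_rank = NA_real_),
              class = "candidate_network")
  })
}

#' @export
print.candidate_network <- function(x, ...) {
  cat(sprintf("<candidate_network> r=%d, %d edges, Q=%s, n_sig=%s, p_res=%s, p_dis=%s\n",
              x$r, nrow(x$edges),
              format(x$modularity_Q, digits = 3), format(x$n_sig),
              format(x$p_resampling, digits = 3),
              format(x$p_disease_enrichment, digits = 3)))
  invisible(x)
}

#' Network resampling p-value
#'
#' Compares the observed link count of the top-r network with the link counts
#' among the top-r genes of each permuted ranking:
#' `p = (1 + #\{perm: links_perm >= observed\}) / (n_perm + 1)`.
#'
#' @param r Network size.
#' @param observed_links Induced link count of the observed top-r network.
#' @param perm_store The `perm_store` element of a `diffusion_result`.
#' @export
network_resampling_pvalue <- function(r, observed_links, perm_store) {
  stopifnot(r >= 1)
  if (r > ncol(perm_store$order)) {
    stopf("r = %d exceeds the stored permutation ranking depth (%d)",
          r, ncol(perm_store$order))
  }
  counts <- perm_link_counts(perm_store, r)
  (1 + sum(counts >= observed_links)) / (length(counts) + 1)
}

# links among the top-r genes of every permuted ranking
perm_link_counts <- function(perm_store, r) {
  n <- length(perm_store$genes)
  n_perm <- nrow(perm_store$order)
  vapply(seq_len(n_perm), function(pm) {
    pos <- rep.int(NA_integer_, n)
    top <- perm_store$order[pm, seq_len(r)]
    pos[top] <- seq_len(r)
    pi_ <- pos[perm_store$edge_i]
    pj <- pos[perm_store$edge_j]
    sum(!is.na(pi_) & !is.na(pj))
  }, 0L)
}

#' Score a candidate network on the four extraction criteria
#'
#' Fills modularity (multilevel communities on the induced subgraph, 0 when
#' edgeless), the number of genes with permutation p below `sig_level`, the
#' network resampling p-value, and the upper-tail hypergeometric p-value of
#' disease-gene enrichment against the interactome universe.
#'
#' @param cand A `candidate_network`.
#' @param result The `diffusion_result` the candidate came from.
#' @param disease_genes Character vector of disease-annotated genes.
#' @param universe Background gene set (defaults to all interactome genes).
#' @param sig_level Per-gene significance cut for `n_sig` (default 0.01).
#' @param seed RNG seed for the community detection.
#' @return The candidate with all four scores populated.
#' @export
score_candidate <- function(cand, result, disease_genes,
                            universe = result$table$gene, sig_level = 0.01,
                            seed = 1L) {
  stopifnot(inherits(cand, "candidate_network"),
            inherits(result, "diffusion_result"))
  disease <- intersect(unique(disease_genes), universe)
  if (!length(disease)) {
    stopf("disease set is disjoint from the universe: background misconfigured")
  }
  if (nrow(cand$edges)) {
    g <- igraph::graph_from_data_frame(cand$edges[, c("gene_a", "gene_b")],
                                       directed = FALSE,
                                       vertices = data.frame(name = cand$genes))
    part <- detect_communities(g, method = "multilevel", seed = seed)
    cand$modularity_Q <- part$Q
    cand$p_resampling <- network_resampling_pvalue(cand$r, nrow(cand$edges),
                                                   result$perm_store)
  } else {
    cand$modularity_Q <- 0
    cand$p_resampling <- 1
  }
  p <- result$table$p[match(cand$genes, result$table$gene)]
  cand$n_sig <- sum(p < sig_level, na.rm = TRUE)
  k <- length(intersect(cand$genes, disease))
  cand$p_disease_enrichment <- hypergeom_pvalue(k, length(disease),
                                                length(cand$genes),
                                                length(universe))
  cand
}

#' Select the top network by equal-weight rank aggregation
#'
#' Each criterion is converted to a rank across candidates (higher Q, higher
#' n_sig, lower resampling p, lower disease-enrichment p are better; average
#' ranks on ties); the composite is their sum and the candidate with the
#' lowest composite wins, smaller r on ties.
#'
#' @param candidates List of scored `candidate_network`s.
#' @param weights Numeric length-4 weights for (Q, n_sig, p_resampling,
#'   p_disease); default equal.
#' @return The winning `candidate_network` with `composite_rank` filled.
#' @export
select_top_network <- function(candidates, weights = c(1, 1, 1, 1)) {
  stopifnot(length(candidates) >= 1, length(weights) == 4)
  tab <- candidate_score_table(candidates)
  if (anyNA(tab[, c("modularity_Q", "n_sig", "p_resampling",
                    "p_disease_enrichment")])) {
    stopf("all four scores must be populated before selection")
  }
  composite <- weights[1] * rank(-tab$modularity_Q) +
    weights[2] * rank(-tab$n_sig) +
    weights[3] * rank(tab$p_resampling) +
    weights[4] * rank(tab$p_disease_enrichment)
  best <- order(composite, tab$r)[1]
  out <- candidates[[best]]
  out$composite_rank <- composite[best]
  out
}

#' @rdname select_top_network
#' @export
candidate_score_table <- function(candidates) {
  data.frame(
    r = as.integer(vapply(candidates, function(cc) as.numeric(cc$r), 0)),
    n_links = vapply(candidates, function(cc) nrow(cc$edges), 0L),
    modularity_Q = vapply(candidates, `[[`, 0, "modularity_Q"),
    n_sig = vapply(candidates, function(cc) as.integer(cc$n_sig), 0L),
    p_resampling = vapply(candidates, `[[`, 0, "p_resampling"),
    p_disease_enrichment = vapply(candidates, `[[`, 0, "p_disease_enrichment"),
    stringsAsFactors = FALSE
  )
}

#' Sweep, score and select the top network in one call
#'
#' @inheritParams candidate_networks
#' @inheritParams score_candidate
#' @param weights Passed to [select_top_network()].
#' @return List with `selected` (the winning candidate), `scores` (the
#'   per-candidate table) and `candidates`.
#' @export
extract_top_network <- function(result, net, disease_genes,
                                universe = result$table$gene,
                                r_min = 50L, r_max = 500L, step = 10L,
                                sig_level = 0.01, seed = 1L,
                                weights = c(1, 1, 1, 1)) {
  cands <- candidate_networks(result, net, r_min, r_max, step)
  cands <- lapply(cands, score_candidate, result = result,
                  disease_genes = disease_genes, universe = universe,
                  sig_level = sig_level, seed = seed)
  sel <- select_top_network(cands, weights)
  list(selected = sel, scores = candidate_score_table(cands),
       candidates = cands)
}
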