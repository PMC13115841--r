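# Independent oracles and shared fixtures.

# Brute-force upper-tail hypergeometric by enumerating all C(N, n) draws.
oracle_hypergeom <- function(k, K, n, N) {
  draws <- utils::combn(N, n)
  annotated <- seq_len(K)
  hits <- apply(draws, 2, function(d) sum(d %in% annotated) >= k)
  mean(hits)
}

# Hand-written BH step-up, independent of stats::p.adjust.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- p[ord] * m / seq_len(m)
  for (i in (m - 1):1) if (m > 1) adj[i] <- min(adj[i], adj[i + 1])
  out <- numeric(m)
  out[ord] <- pmin(adj, 1)
  out
}

# interactome straight from an edge table (scores already combined)
interactome_from_edges <- function(gene_a, gene_b, score = 800) {
  build_interactome(data.frame(node_a = gene_a, node_b = gene_b,
                               score = score, stringsAsFactors = FALSE))
}

# random connected-ish ER interactome for numeric property tests
random_interactome <- function(n = 50, p = 0.12, seed = 1) {
  set.seed(seed)
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  keep <- runif(nrow(idx)) < p
  genes <- sprintf("g%02d", seq_len(n))
  interactome_from_edges(genes[idx[keep, 1]], genes[idx[keep, 2]])
}

# One shared run of the default planted benchmark (computed once per session).
.fixtures <- new.env(parent = emptyenv())
planted_run <- function() {
  if (is.null(.fixtures$planted)) {
    bench <- generate_benchmark(benchmark_config(rng_seed = 1L))
    net <- build_interactome(recombine_links(bench$links), bench$mapping)
    W <- normalize_adjacency(net)
    x0 <- seed_vector(net, bench$seeds)
    result <- permutation_adjusted_index(W, x0, n_perm = 200L, seed = 2L,
                                         store_top = min(500L, length(net$genes)))
    ext <- extract_top_network(result, net, bench$disease,
                               r_max = min(500L, length(net$genes)), seed = 3L)
    .fixtures$planted <- list(bench = bench, net = net, W = W, x0 = x0,
                              result = result, ext = ext)
  }
  .fixtures$planted
}

# benchmark -> planted-module recall of the selected network
pipeline_recall <- function(module_p, rng_seed, n_perm = 100L) {
  bench <- generate_benchmark(benchmark_config(module_p = module_p,
                                               rng_seed = rng_seed))
  net <- build_interactome(recombine_links(bench$links), bench$mapping)
  W <- normalize_adjacency(net)
  x0 <- seed_vector(net, bench$seeds)
  res <- permutation_adjusted_index(W, x0, n_perm = n_perm,
                                    seed = rng_seed + 1L,
                                    store_top = min(500L, length(net$genes)))
  ext <- extract_top_network(res, net, bench$disease,
                             r_max = min(500L, length(net$genes)),
                             seed = rng_seed + 2L)
  mean(bench$truth$module %in% ext$selected$genes)
}
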