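#' Newman--Girvan modularity of a partition
#'
#' `Q = sum_c (e_c/m - (d_c/2m)^2)` over communities c, with e_c the
#' within-community edge count, d_c the community degree sum and m the total
#' edge count. An edgeless graph has Q = 0 by convention.
#'
#' @param graph An undirected igraph graph.
#' @param membership Community id per vertex (vector, in vertex order).
#' @return Modularity Q in `[-0.5, 1]`.
#' @export
modularity_q <- function(graph, membership) {
  stopifnot(igraph::vcount(graph) == length(membership))
  if (igraph::ecount(graph) == 0) return(0)
  igraph::modularity(graph, as.integer(factor(membership)))
}

#' Community detection (multilevel or fastgreedy)
#'
#' Multilevel is Louvain-style modularity optimization (stochastic; made
#' reproducible by the `seed`); fastgreedy is deterministic agglomerative
#' modularity optimization. Neither merges disconnected components (such a
#' merge always lowers Q).
#'
#' @param graph Undirected igraph graph.
#' @param method `"multilevel"` (default) or `"fastgreedy"`.
#' @param seed RNG seed for the stochastic method.
#' @return Object of class `community_partition`: list with `membership`
#'   (named integer vector), `method`, `Q`.
#' @export
detect_communities <- function(graph, method = c("multilevel", "fastgreedy"),
                               seed = 1L) {
  method <- match.arg(method)
  if (igraph::ecount(graph) == 0) {
    memb <- seq_len(igraph::vcount(graph))
  } else {
    comm <- with_local_seed(seed, {
      if (method == "multilevel") {
        igraph::cluster_louvain(graph, weights = NA)
      } else {
        igraph::cluster_fast_greedy(graph, weights = NA)
      }
    })
    memb <- igraph::membership(comm)
  }
  memb <- stats::setNames(as.integer(memb), igraph::V(graph)$name)
  structure(list(membership = memb, method = method,
                 Q = modularity_q(graph, memb)),
            class = "community_partition")
}

#' @export
print.community_partition <- function(x, ...) {
  cat(sprintf("<community_partition> %s: %d communities, Q = %.3f\n",
              x$method, length(unique(x$membership)), x$Q))
  invisible(x)
}

#' Functional cartography: within-community degree z and participation P
#'
#' For gene i in community s, `z = (kappa_i - mean_s kappa) / sd_s kappa`
#' where kappa is the within-community link count (mean and sd over the
#' members of s, the gene included; sd 0 gives z = 0), and
#' `P = 1 - sum_s (k_is/k_i)^2` over communities s. Roles: nonhubs
#' (z < z_hub) split by P at `p_cuts_nonhub` into R1 (ultraperipheral), R2
#' (peripheral), R3 (nonhub connector), R4 (nonhub kinless); hubs (z >= z_hub)
#' split at `p_cuts_hub` into R5 (provincial hub), R6 (connector hub), R7
#' (kinless hub). Cut comparisons use `P <= cut`. Isolated genes get
#' P = 0, z = 0, role R1.
#'
#' @param graph Undirected igraph graph.
#' @param partition A `community_partition` (or membership vector in vertex
#'   order).
#' @param z_hub Hub threshold on z (default 2.5).
#' @param p_cuts_nonhub,p_cuts_hub Increasing P cut points.
#' @return `data.frame` with gene, community, degree, z, P, role.
#' @export
cartography_profiles <- function(graph, partition, z_hub = 2.5,
                                 p_cuts_nonhub = c(0.05, 0.62, 0.80),
                                 p_cuts_hub = c(0.30, 0.75)) {
  memb <- if (inherits(partition, "community_partition")) {
    partition$membership
  } else {
    stats::setNames(as.integer(partition), igraph::V(graph)$name)
  }
  n <- igraph::vcount(graph)
  stopifnot(length(memb) == n)
  genes <- igraph::V(graph)$name
  memb <- memb[genes]
  el <- igraph::as_edgelist(graph, names = FALSE)
  deg <- igraph::degree(graph)

  # k_is: links of vertex v into community s
  kis <- matrix(0L, nrow = n, ncol = length(unique(memb)),
                dimnames = list(genes, sort(unique(memb))))
  if (nrow(el)) {
    ci <- as.character(memb[el[, 2]])
    cj <- as.character(memb[el[, 1]])
    for (e in seq_len(nrow(el))) {
      kis[el[e, 1], ci[e]] <- kis[el[e, 1], ci[e]] + 1L
      kis[el[e, 2], cj[e]] <- kis[el[e, 2], cj[e]] + 1L
    }
  }
  own <- as.character(memb)
  kappa <- kis[cbind(seq_len(n), match(own, colnames(kis)))]
  mu <- stats::ave(kappa, memb, FUN = mean)
  sdv <- stats::ave(kappa, memb, FUN = stats::sd)
  sdv[is.na(sdv)] <- 0
  z <- ifelse(sdv > 0, (kappa - mu) / sdv, 0)
  P <- ifelse(deg > 0, 1 - rowSums((kis / pmax(deg, 1))^2), 0)

  role <- character(n)
  hub <- z >= z_hub
  nb <- findInterval(P[!hub], p_cuts_nonhub, left.open = TRUE)
  role[!hub] <- paste0("R", nb + 1L)
  hb <- findInterval(P[hub], p_cuts_hub, left.open = TRUE)
  role[hub] <- paste0("R", hb + 5L)

  data.frame(gene = genes, community = as.integer(memb), degree = as.integer(deg),
             z = z, P = P, role = role, stringsAsFactors = FALSE)
}
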