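#' Seed vector over the interactome genes
#'
#' Builds the initial weight vector x0: 1 for seed genes present in the
#' network, 0 elsewhere. Seeds absent from the network are reported and
#' dropped.
#'
#' @param net An `interactome` (or character vector of gene ids).
#' @param seeds Character vector of seed gene identifiers.
#' @return Named numeric vector in `{0,1}` over network genes, with attribute
#'   `n_seeds`.
#' @export
seed_vector <- function(net, seeds) {
  genes <- if (inherits(net, "interactome")) net$genes else as.character(net)
  seeds <- unique(as.character(seeds))
  missing <- setdiff(seeds, genes)
  if (length(missing)) {
    message(sprintf("seed_vector: %d of %d seeds not in the network, dropped",
                    length(missing), length(seeds)))
  }
  x0 <- stats::setNames(as.numeric(genes %in% seeds), genes)
  if (sum(x0) < 1) stopf("no seed genes present in the network")
  attr(x0, "n_seeds") <- as.integer(sum(x0))
  x0
}

#' Network diffusion to the damped steady state
#'
#' Propagates the seed vector over the symmetrically normalized adjacency W to
#' the steady state of the damped random walk,
#' `xs = (1 - alpha) (I - alpha W)^{-1} x0`, equivalently the geometric series
#' `(1 - alpha) * sum_k alpha^k W^k x0`. The undamped inverse `(I - W)^{-1}`
#' is singular on components containing seeds (W has a unit eigenvalue there),
#' so the damped form is the one solved.
#'
#' @param W Symmetric normalized adjacency (from [normalize_adjacency()]).
#' @param x0 Seed vector over the same genes (from [seed_vector()]).
#' @param alpha Diffusion weight in (0,1); default 0.7.
#' @param method `"solve"` (sparse direct solve, default) or `"series"`
#'   (power iteration to `tol` in max norm).
#' @param tol,max_iter Series stopping controls.
#' @return Named numeric vector xs (all entries >= 0).
#' @export
diffuse <- function(W, x0, alpha = 0.7, method = c("solve", "series"),
                    tol = 1e-10, max_iter = 100000L) {
  method <- match.arg(method)
  n <- nrow(W)
  stopifnot(n == ncol(W), length(x0) == n, alpha >= 0, alpha < 1)
  x0 <- as.numeric(x0)
  if (method == "solve") {
    M <- Matrix::Diagonal(n) - alpha * W
    xs <- as.numeric(Matrix::solve(M, x0))
    xs <- (1 - alpha) * xs
  } else {
    term <- x0
    acc <- x0
    for (k in seq_len(max_iter)) {
      term <- alpha * as.numeric(W %*% term)
      acc <- acc + term
      if (max(abs(term)) < tol) break
    }
    xs <- (1 - alpha) * acc
  }
  xs[xs < 0 & xs > -1e-14] <- 0   # clip solver noise
  stats::setNames(xs, rownames(W))
}

#' Network smoothing index
#'
#' `Si = xs / (x0 + epsilon)` elementwise: the steady-state score discounted
#' by initial membership, so seeds with little network support are
#' de-emphasized as epsilon grows.
#'
#' @param xs Steady-state vector from [diffuse()].
#' @param x0 Seed vector.
#' @param epsilon Positive smoothing offset (default 50).
#' @return Named numeric vector Si.
#' @export
smoothing_index <- function(xs, x0, epsilon = 50) {
  stopifnot(epsilon > 0, length(xs) == length(x0))
  stats::setNames(as.numeric(xs) / (as.numeric(x0) + epsilon), names(xs))
}

#' Permutation-adjusted network smoothing index
#'
#' Recomputes the smoothing index under `n_perm` uniform permutations of the
#' seed labels over all network genes (seed count preserved), derives per-gene
#' permutation p-values with a pseudocount,
#' `p_i = (1 + #\{Si_perm >= Si_obs\}) / (n_perm + 1)`, and the adjusted index
#' `S~_i = -Si * log10(p_i)`. The per-permutation top rankings (by decreasing
#' permuted Si) are retained for network resampling.
#'
#' @inheritParams diffuse
#' @param epsilon Smoothing offset passed to [smoothing_index()].
#' @param n_perm Number of permutations (default 1000).
#' @param seed RNG seed stored in the result for exact replay.
#' @param degree_matched If `TRUE`, permute seed labels within degree bins
#'   (deciles of degree) instead of uniformly. Off by default.
#' @param store_top How many top genes of each permuted ranking to keep for
#'   resampling (default 500).
#' @return Object of class `diffusion_result`: list with `table` (data.frame
#'   gene, x0, xs, Si, p, S_tilde, rank), `ranking` (gene ids by decreasing
#'   S~, ties broken by higher xs then gene id), `alpha`, `epsilon`,
#'   `n_perm`, `seed`, and `perm_store` for [network_resampling_pvalue()].
#' @export
permutation_adjusted_index <- function(W, x0, alpha = 0.7, epsilon = 50,
                                       n_perm = 1000L, seed = 1L,
                                       degree_matched = FALSE,
                                       store_top = 500L) {
  n <- nrow(W)
  stopifnot(length(x0) == n)
  if (n_perm < 1) stopf("n_perm must be >= 1 (p-values undefined otherwise)")
  genes <- rownames(W)
  x0 <- as.numeric(x0)

  M <- Matrix::Diagonal(n) - alpha * W
  ch <- Matrix::Cholesky(Matrix::forceSymmetric(M), perm = TRUE, LDL = FALSE)
  solve_many <- function(B) {
    (1 - alpha) * as.matrix(Matrix::solve(ch, B, system = "A"))
  }
  xs <- as.numeric(solve_many(matrix(x0, ncol = 1)))
  xs[xs < 0 & xs > -1e-14] <- 0
  Si <- xs / (x0 + epsilon)

  degree_bin <- NULL
  if (degree_matched) {
    deg <- Matrix::rowSums(W != 0)
    degree_bin <- cut(rank(deg, ties.method = "first"), breaks = 10,
                      labels = FALSE)
  }

  store_top <- min(as.integer(store_top), n)
  perm_order <- matrix(0L, nrow = n_perm, ncol = store_top)
  count_ge <- numeric(n)
  chunk <- 200L
  with_local_seed(seed, {
    done <- 0L
    while (done < n_perm) {
      k <- min(chunk, n_perm - done)
      X0 <- matrix(0, n, k)
      for (j in seq_len(k)) {
        if (degree_matched) {
          idx <- unlist(lapply(split(seq_len(n), degree_bin), function(ix) {
            ix[sample.int(length(ix))]
          }), use.names = FALSE)
          ord <- unlist(split(seq_len(n), degree_bin), use.names = FALSE)
          perm <- integer(n); perm[ord] <- idx
          X0[, j] <- x0[perm]
        } else {
          X0[, j] <- x0[sample.int(n)]
        }
      }
      XS <- solve_many(X0)
      SiP <- XS / (X0 + epsilon)
      count_ge <- count_ge + rowSums(SiP >= (Si - 1e-12))
      for (j in seq_len(k)) {
        o <- order(-SiP[, j], genes)
        perm_order[done + j, ] <- o[seq_len(store_top)]
      }
      done <- done + k
    }
  })

  p <- (1 + count_ge) / (n_perm + 1)
  S_tilde <- -Si * log10(p)
  ord <- order(-S_tilde, -xs, genes)
  tab <- data.frame(gene = genes, x0 = x0, xs = xs, Si = Si, p = p,
                    S_tilde = S_tilde, stringsAsFactors = FALSE)
  tab$rank <- match(seq_len(n), ord)
  ut <- upper_edges(W)
  structure(list(table = tab, ranking = genes[ord], alpha = alpha,
                 epsilon = epsilon, n_perm = as.integer(n_perm),
                 seed = as.integer(seed),
                 perm_store = list(order = perm_order, genes = genes,
                                   edge_i = ut$i, edge_j = ut$j)),
            class = "diffusion_result")
}

#' @export
print.diffusion_result <- function(x, ...) {
  cat(sprintf("<diffusion_result> %d genes, alpha=%g, epsilon=%g, %d permutations (seed %d)\n",
              nrow(x$table), x$alpha, x$epsilon, x$n_perm, x$seed))
  invisible(x)
}

# upper-triangle nonzero pattern of W as integer edge endpoints
upper_edges <- function(W) {
  T <- methods::as(methods::as(Matrix::triu(W, k = 1), "generalMatrix"),
                   "TsparseMatrix")
  list(i = T@i + 1L, j = T@j + 1L)
}

#' Select the smoothing offset epsilon
#'
#' For each candidate epsilon, genes are ranked by decreasing Si(epsilon); the
#' objective is the number of seed genes among the top `top_k` that are
#' connected (non-isolated) within the subgraph induced by those top genes.
#' Returns the epsilon maximizing the objective, smallest on ties; the
#' objective curve is attached as attribute `"objective"`.
#'
#' @inheritParams diffuse
#' @param eps_grid Candidate epsilon values.
#' @param top_k Number of top-ranked genes scanned (default 500).
#' @export
select_epsilon <- function(W, x0, alpha = 0.7,
                           eps_grid = c(1, 10, 50, 100, 500), top_k = 500L) {
  stopifnot(length(eps_grid) >= 1)
  n <- nrow(W)
  top_k <- min(as.integer(top_k), n)
  genes <- rownames(W)
  x0 <- as.numeric(x0)
  xs <- diffuse(W, x0, alpha)
  ut <- upper_edges(W)
  obj <- vapply(eps_grid, function(eps) {
    Si <- xs / (x0 + eps)
    top <- order(-Si, genes)[seq_len(top_k)]
    intop <- logical(n); intop[top] <- TRUE
    keep <- intop[ut$i] & intop[ut$j]
    connected <- logical(n)
    connected[ut$i[keep]] <- TRUE
    connected[ut$j[keep]] <- TRUE
    sum(x0[top] == 1 & connected[top])
  }, 0)
  eps <- eps_grid[order(-obj, eps_grid)][1]
  attr(eps, "objective") <- stats::setNames(obj, eps_grid)
  eps
}
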