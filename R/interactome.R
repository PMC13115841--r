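#' Recombine STRING evidence-channel scores
#'
#' Implements the standard STRING score combination on the 0--1000 scale with
#' an optional set of excluded channels: each included channel score s is
#' rescaled to `[0,1]`, the channel prior p is removed,
#' `s' = max(0, (s/1000 - p)/(1 - p))`, the de-priored channels are combined as
#' `c = 1 - prod(1 - s')`, and the prior is added back,
#' `t = c*(1 - p) + p`, returned as `round(1000*t)`.
#'
#' @param channel_scores Named numeric vector of channel scores in `[0,1000]`.
#' @param excluded_channels Character vector of channel names to ignore
#'   (e.g. `"textmining"`).
#' @param prior Prior probability of a functional interaction (STRING uses
#'   0.041).
#' @return Integer combined score in `[0,1000]`.
#' @examples
#' recombine_scores(c(experiments = 500, database = 500))      # 739
#' recombine_scores(c(textmining = 900), "textmining")         # 41
#' @export
recombine_scores <- function(channel_scores, excluded_channels = character(),
                             prior = 0.041) {
  stopifnot(is.numeric(channel_scores), prior > 0, prior < 1)
  if (any(channel_scores < 0 | channel_scores > 1000)) {
    stopf("channel scores must lie in [0, 1000]")
  }
  keep <- !(names(channel_scores) %in% excluded_channels)
  s <- channel_scores[keep] / 1000
  sp <- pmax(0, (s - prior) / (1 - prior))
  cc <- 1 - prod(1 - sp)
  as.integer(round(1000 * (cc * (1 - prior) + prior)))
}

#' @rdname recombine_scores
#' @param links Links table from [read_string_links()]; recombined rowwise
#'   over its channel columns (the `combined_score` column is ignored).
#' @return `recombine_links`: `data.frame` with `node_a`, `node_b`, `score`.
#' @export
recombine_links <- function(links, excluded_channels = "textmining",
                            prior = 0.041) {
  stopifnot(prior > 0, prior < 1)
  channels <- setdiff(names(links)[-(1:2)], c("combined_score", excluded_channels))
  if (!length(channels)) stopf("no evidence channels left after exclusion")
  m <- as.matrix(links[, channels, drop = FALSE]) / 1000
  if (any(m < 0 | m > 1)) stopf("channel scores must lie in [0, 1000]")
  sp <- (m - prior) / (1 - prior)
  sp[sp < 0] <- 0
  cc <- 1 - exp(rowSums(log1p(-sp)))
  data.frame(node_a = as.character(links[[1]]), node_b = as.character(links[[2]]),
             score = as.integer(round(1000 * (cc * (1 - prior) + prior))),
             stringsAsFactors = FALSE)
}

#' Build the filtered analysis interactome
#'
#' Applies the edge-retention policy to a scored edge table: identifiers are
#' mapped to gene ids (unmapped records dropped with a reported count),
#' self-loops removed, duplicate gene pairs collapsed to their maximum score,
#' and an edge is retained when its score reaches `high_threshold`, or when it
#' is among the `top_k_medium` medium-confidence edges
#' (`medium_threshold <= score < high_threshold`) of either endpoint, ranked
#' by descending score with ties broken by lexicographic partner id.
#'
#' @param edges `data.frame` with columns `node_a`, `node_b`, `score`
#'   (0--1000), e.g. from [recombine_links()] applied to
#'   [read_string_links()] output.
#' @param mapping Optional named character vector (protein id -> gene id);
#'   `NULL` means identifiers are already gene ids.
#' @param high_threshold Combined score at or above which an edge is always
#'   kept (default 700, STRING "high confidence").
#' @param medium_threshold Minimum score for the per-gene top-k rescue
#'   (default 400, STRING "medium confidence").
#' @param top_k_medium Number of medium-confidence edges rescued per gene
#'   (default 3).
#' @return An object of class `interactome`: list with `genes` (sorted
#'   character vector) and `edges` (`data.frame` `gene_a < gene_b`, `score`).
#' @export
build_interactome <- function(edges, mapping = NULL, high_threshold = 700,
                              medium_threshold = 400, top_k_medium = 3) {
  stopifnot(medium_threshold <= high_threshold, top_k_medium >= 0)
  need <- c("node_a", "node_b", "score")
  if (!all(need %in% names(edges))) {
    stopf("edges needs columns %s", paste(need, collapse = ", "))
  }
  if (nrow(edges) == 0) return(new_interactome(character(), empty_edges()))
  if (any(edges$score < 0 | edges$score > 1000)) {
    stopf("edge scores must lie in [0, 1000]")
  }
  a <- as.character(edges$node_a)
  b <- as.character(edges$node_b)
  s <- as.integer(edges$score)
  if (!is.null(mapping)) {
    ga <- unname(mapping[a]); gb <- unname(mapping[b])
    unmapped <- is.na(ga) | is.na(gb)
    if (any(unmapped)) {
      message(sprintf("build_interactome: dropped %d records with unmapped identifiers",
                      sum(unmapped)))
    }
    a <- ga[!unmapped]; b <- gb[!unmapped]; s <- s[!unmapped]
  }
  keep <- a != b
  a <- a[keep]; b <- b[keep]; s <- s[keep]
  if (!length(a)) return(new_interactome(character(), empty_edges()))
  ga <- pmin(a, b); gb <- pmax(a, b)
  # duplicate gene pairs (incl. both orientations, multi-mapping): max score
  key <- paste(ga, gb, sep = "\r")
  mx <- tapply(s, key, max)
  pairs <- strsplit(names(mx), "\r", fixed = TRUE)
  ga <- vapply(pairs, `[[`, "", 1L)
  gb <- vapply(pairs, `[[`, "", 2L)
  s <- as.integer(mx)

  high <- s >= high_threshold
  medium <- s >= medium_threshold & s < high_threshold
  rescued <- rep(FALSE, length(s))
  if (any(medium) && top_k_medium > 0) {
    idx <- which(medium)
    # each medium edge appears once per endpoint
    ends <- c(ga[idx], gb[idx])
    eidx <- c(idx, idx)
    partner <- c(gb[idx], ga[idx])
    ord <- order(ends, -s[eidx], partner)
    ends <- ends[ord]; eidx <- eidx[ord]
    rk <- stats::ave(seq_along(ends), ends, FUN = seq_along)
    rescued[unique(eidx[rk <= top_k_medium])] <- TRUE
  }
  sel <- high | rescued
  ed <- data.frame(gene_a = ga[sel], gene_b = gb[sel], score = s[sel],
                   stringsAsFactors = FALSE)
  ed <- ed[order(ed$gene_a, ed$gene_b), , drop = FALSE]
  rownames(ed) <- NULL
  new_interactome(sort(unique(c(ed$gene_a, ed$gene_b))), ed)
}

empty_edges <- function() {
  data.frame(gene_a = character(), gene_b = character(), score = integer(),
             stringsAsFactors = FALSE)
}

new_interactome <- function(genes, edges) {
  structure(list(genes = genes, edges = edges), class = "interactome")
}

#' @export
print.interactome <- function(x, ...) {
  cat(sprintf("<interactome> %d genes, %d edges\n",
              length(x$genes), nrow(x$edges)))
  invisible(x)
}

#' Convert an interactome to an igraph graph
#'
#' @param net An `interactome`.
#' @param weighted Attach `score` as the `weight` edge attribute.
#' @return An undirected [igraph::igraph] graph over all interactome genes
#'   (isolated genes included).
#' @export
as_igraph <- function(net, weighted = TRUE) {
  stopifnot(inherits(net, "interactome"))
  g <- igraph::graph_from_data_frame(net$edges[, c("gene_a", "gene_b")],
                                     directed = FALSE,
                                     vertices = data.frame(name = net$genes))
  if (weighted && nrow(net$edges)) {
    igraph::E(g)$weight <- net$edges$score
  }
  g
}

#' Symmetrically normalized adjacency matrix
#'
#' Returns `W = D^(-1/2) A D^(-1/2)` as a sparse symmetric matrix with gene
#' dimnames. Rows/columns of isolated genes are zero (0/0 taken as 0). With
#' `weighting = "binary"` A is the 0/1 adjacency; with `"score"` A carries
#' `score/1000` weights.
#'
#' @param net An `interactome`.
#' @param weighting `"binary"` (default) or `"score"`.
#' @return A sparse symmetric [Matrix::Matrix] with spectral radius <= 1.
#' @export
normalize_adjacency <- function(net, weighting = c("binary", "score")) {
  stopifnot(inherits(net, "interactome"))
  weighting <- match.arg(weighting)
  genes <- net$genes
  n <- length(genes)
  if (n == 0) stopf("empty interactome")
  i <- match(net$edges$gene_a, genes)
  j <- match(net$edges$gene_b, genes)
  w <- if (weighting == "binary") rep(1, length(i)) else net$edges$score / 1000
  A <- Matrix::sparseMatrix(i = c(i, j), j = c(j, i), x = c(w, w),
                            dims = c(n, n), dimnames = list(genes, genes))
  d <- Matrix::rowSums(A)
  dinv <- ifelse(d > 0, 1 / sqrt(d), 0)
  W <- Matrix::Diagonal(n, dinv) %*% A %*% Matrix::Diagonal(n, dinv)
  W <- Matrix::forceSymmetric(W)
  dimnames(W) <- list(genes, genes)
  W
}
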