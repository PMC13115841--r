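#' Chromosomal band enrichment of a gene set
#'
#' One upper-tail hypergeometric test per cytoband (K = annotated universe
#' genes on the band, k = network genes on the band), BH-corrected across
#' bands. Genes without a locus are excluded from the universe with a
#' reported count.
#'
#' @param network_genes Character vector of genes to test.
#' @param loci Locus table (see [read_loci()]).
#' @param universe Background gene set.
#' @param fdr_max Bands with `fdr < fdr_max` are flagged significant
#'   (default 0.25).
#' @return Enrichment table with `set` (band), `k`, `K`, `n`, `N`, `p`,
#'   `fdr`, `overlap`, `significant`.
#' @export
band_enrichment <- function(network_genes, loci, universe, fdr_max = 0.25) {
  validate_loci(loci)
  universe <- unique(as.character(universe))
  annotated <- intersect(universe, loci$gene)
  dropped <- length(universe) - length(annotated)
  if (dropped > 0) {
    message(sprintf("band_enrichment: %d universe genes without loci excluded",
                    dropped))
  }
  net <- intersect(unique(network_genes), annotated)
  if (!length(net)) {
    warning("no annotated network genes")
    return(data.frame(set = character(), k = integer(), K = integer(),
                      n = integer(), N = integer(), p = numeric(),
                      fdr = numeric(), overlap = character(),
                      significant = logical(), stringsAsFactors = FALSE))
  }
  band <- stats::setNames(paste0(loci$chrom, loci$band), loci$gene)
  bands <- split(annotated, band[annotated])
  collection <- bands
  tab <- pathway_ora(net, collection, annotated, min_size = 1L,
                     max_size = length(annotated))
  tab$significant <- tab$fdr < fdr_max
  tab
}

#' Genomic neighbors within a linkage window
#'
#' Emits a pair for every (network gene, target gene) on the same chromosome
#' whose spans are within `window_bp` of each other (gap between closest
#' ends; 0 when spans overlap; the boundary is inclusive). Genetic distance
#' uses the uniform 1 cM = 1e6 bp conversion.
#'
#' @param network_genes,target_genes Character vectors; both must be
#'   annotated in `loci` (unannotated genes are skipped).
#' @param loci Locus table.
#' @param window_bp Window in bp (default 500000, i.e. 0.5 cM).
#' @return `data.frame` with `network_gene`, `neighbor`, `distance_bp`,
#'   `distance_cM`, sorted by network gene then distance.
#' @export
linkage_neighbors <- function(network_genes, target_genes, loci,
                              window_bp = 500000) {
  validate_loci(loci)
  net <- intersect(unique(network_genes), loci$gene)
  tgt <- intersect(unique(target_genes), loci$gene)
  li <- loci[match(net, loci$gene), ]
  lj <- loci[match(tgt, loci$gene), ]
  out <- list()
  for (a in seq_along(net)) {
    same <- lj$chrom == li$chrom[a] & lj$gene != li$gene[a]
    if (!any(same)) next
    cand <- lj[same, ]
    gap <- pmax(0, pmax(cand$start - li$end[a], li$start[a] - cand$end))
    hit <- gap <= window_bp
    if (!any(hit)) next
    out[[length(out) + 1L]] <- data.frame(
      network_gene = li$gene[a], neighbor = cand$gene[hit],
      distance_bp = as.numeric(gap[hit]),
      distance_cM = as.numeric(gap[hit]) / 1e6,
      stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    return(data.frame(network_gene = character(), neighbor = character(),
                      distance_bp = numeric(), distance_cM = numeric(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$network_gene, res$distance_bp, res$neighbor), ]
  rownames(res) <- NULL
  res
}

#' HAR-gene overlap report
#'
#' Pure set algebra: which network genes are HAR-regulated, and of those,
#' which are already disease-annotated versus newly inferred.
#'
#' @param network_genes,har_genes,disease_genes Character vectors
#'   (duplicates ignored).
#' @return List with `network_har`, `network_har_disease`,
#'   `network_har_inferred` (sorted character vectors) and `counts`
#'   (named integer vector).
#' @export
har_overlap <- function(network_genes, har_genes, disease_genes = character()) {
  net <- unique(as.character(network_genes))
  har <- unique(as.character(har_genes))
  dis <- unique(as.character(disease_genes))
  nh <- sort(intersect(net, har))
  nhd <- sort(intersect(nh, dis))
  nhi <- sort(setdiff(nh, dis))
  list(network_har = nh, network_har_disease = nhd, network_har_inferred = nhi,
       counts = c(network_har = length(nh), network_har_disease = length(nhd),
                  network_har_inferred = length(nhi)))
}
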