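#' Pipeline configuration
#'
#' Bundles all input paths and analysis parameters with the pipeline's
#' defaults: diffusion weight `alpha = 0.7`, smoothing offset `epsilon = 50`,
#' 1000 permutations, extraction sweep r in `[50, 500]` step 10, interactome
#' thresholds 700/400/top-3, ORA FDR 0.05, band FDR 0.25, and a 0.5 cM
#' (500 kb) linkage window.
#'
#' @param links,mapping,seeds,disease,deg,pathways,loci,har Input file paths
#'   (see the corresponding readers). `deg`, `pathways`, `loci`, `har` are
#'   optional (`NULL` skips that annotation stage).
#' @param alpha,epsilon,n_perm,r_min,r_max,step Diffusion and extraction
#'   parameters.
#' @param high_threshold,medium_threshold,top_k_medium Interactome retention.
#' @param excluded_channels Evidence channels excluded from recombination.
#' @param ora_fdr,band_fdr,window_bp Annotation thresholds.
#' @param rng_seed Top-level RNG seed; stage seeds are derived from it.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(links, mapping = NULL, seeds, disease,
                            deg = NULL, pathways = NULL, loci = NULL,
                            har = NULL,
                            alpha = 0.7, epsilon = 50, n_perm = 1000L,
                            r_min = 50L, r_max = 500L, step = 10L,
                            high_threshold = 700, medium_threshold = 400,
                            top_k_medium = 3L,
                            excluded_channels = "textmining",
                            ora_fdr = 0.05, band_fdr = 0.25,
                            window_bp = 500000, rng_seed = 1L) {
  structure(list(links = links, mapping = mapping, seeds = seeds,
                 disease = disease, deg = deg, pathways = pathways,
                 loci = loci, har = har, alpha = alpha, epsilon = epsilon,
                 n_perm = as.integer(n_perm), r_min = as.integer(r_min),
                 r_max = as.integer(r_max), step = as.integer(step),
                 high_threshold = high_threshold,
                 medium_threshold = medium_threshold,
                 top_k_medium = as.integer(top_k_medium),
                 excluded_channels = excluded_channels,
                 ora_fdr = ora_fdr, band_fdr = band_fdr,
                 window_bp = window_bp, rng_seed = as.integer(rng_seed)),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML file whose keys match the `pipeline_config()` arguments.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals)
}

#' Run the whole pipeline end to end
#'
#' build-net -> diffuse -> extract -> cartography -> enrich -> genomics, with
#' per-stage outputs under `out_dir` and a machine-readable `summary.json`.
#' Every threshold actually used is logged via `message()`. Stage RNG seeds
#' are derived from `config$rng_seed` by fixed offsets (diffusion +1,
#' community detection +2).
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the stage objects (`interactome`,
#'   `diffusion`, `extraction`, `partition`, `cartography`, `ora`, `meta`,
#'   `bands`, `linkage`, `har`, `summary`).
#' @export
run_all <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  for (f in c("links", "seeds", "disease")) {
    if (is.null(config[[f]])) stopf("stage build-net: required input '%s' missing", f)
  }
  inputs <- c("links", "mapping", "seeds", "disease", "deg", "pathways",
              "loci", "har")
  for (f in inputs) {
    if (!is.null(config[[f]]) && !file.exists(config[[f]])) {
      stopf("stage %s: input file not found: %s",
            if (f %in% c("links", "mapping")) "build-net" else f, config[[f]])
    }
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  message(sprintf(
    "build-net: high>=%g, medium>=%g, top_k=%d, excluded=%s, prior=0.041",
    config$high_threshold, config$medium_threshold, config$top_k_medium,
    paste(config$excluded_channels, collapse = ",")))
  links <- read_string_links(config$links)
  scored <- recombine_links(links, config$excluded_channels)
  mapping <- if (!is.null(config$mapping)) read_id_mapping(config$mapping)
  net <- build_interactome(scored, mapping,
                           high_threshold = config$high_threshold,
                           medium_threshold = config$medium_threshold,
                           top_k_medium = config$top_k_medium)
  if (!length(net$genes)) stopf("stage build-net: empty interactome")
  write_edge_tsv(net$edges, file.path(out_dir, "network_edges.tsv"))

  message(sprintf("diffuse: alpha=%g, epsilon=%g, n_perm=%d, seed=%d",
                  config$alpha, config$epsilon, config$n_perm,
                  config$rng_seed + 1L))
  W <- normalize_adjacency(net)
  seeds <- read_gene_list(config$seeds)
  x0 <- seed_vector(net, seeds)
  r_max <- min(config$r_max, length(net$genes))
  if (r_max < config$r_max) {
    message(sprintf("extract: r_max clamped to %d (network size)", r_max))
  }
  result <- permutation_adjusted_index(W, x0, alpha = config$alpha,
                                       epsilon = config$epsilon,
                                       n_perm = config$n_perm,
                                       seed = config$rng_seed + 1L,
                                       store_top = r_max)
  utils::write.table(result$table, file.path(out_dir, "diffusion.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  message(sprintf("extract: r in [%d, %d] step %d, sig p<0.01",
                  config$r_min, r_max, config$step))
  disease <- read_gene_list(config$disease)
  ext <- extract_top_network(result, net, disease,
                             r_min = min(config$r_min, r_max), r_max = r_max,
                             step = config$step, seed = config$rng_seed + 2L)
  sel <- ext$selected
  write_edge_tsv(sel$edges, file.path(out_dir, "top_network.tsv"))
  write_gene_list(sel$genes, file.path(out_dir, "top_network_genes.txt"))
  utils::write.table(ext$scores, file.path(out_dir, "candidate_scores.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  g <- igraph::graph_from_data_frame(sel$edges[, c("gene_a", "gene_b")],
                                     directed = FALSE,
                                     vertices = data.frame(name = sel$genes))
  part <- detect_communities(g, "multilevel", seed = config$rng_seed + 2L)
  carto <- cartography_profiles(g, part)
  utils::write.table(carto, file.path(out_dir, "roles.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  comp <- igraph::components(g)

  ora <- meta <- NULL
  if (!is.null(config$pathways)) {
    message(sprintf("enrich: min 3 / max 200 genes, fdr<%g, meta >=3 genes",
                    config$ora_fdr))
    pw <- read_gmt(config$pathways)
    ora <- pathway_ora(sel$genes, pw, universe = net$genes)
    utils::write.table(ora, file.path(out_dir, "ora.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    meta <- meta_pathways(ora, pw, fdr_max = config$ora_fdr)
    utils::write.table(
      data.frame(pathway = names(meta$clusters),
                 meta_pathway = unname(meta$clusters)),
      file.path(out_dir, "meta_pathways.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
  }

  bands <- linkage <- harrep <- NULL
  if (!is.null(config$loci)) {
    message(sprintf("genomics: band fdr<%g, window=%g bp",
                    config$band_fdr, config$window_bp))
    loci <- read_loci(config$loci)
    bands <- band_enrichment(sel$genes, loci, universe = net$genes,
                             fdr_max = config$band_fdr)
    utils::write.table(bands, file.path(out_dir, "band_enrichment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    linkage <- linkage_neighbors(sel$genes, disease, loci,
                                 window_bp = config$window_bp)
    utils::write.table(linkage, file.path(out_dir, "linkage_pairs.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(config$har)) {
    harrep <- har_overlap(sel$genes, read_gene_list(config$har), disease)
    write_gene_list(harrep$network_har, file.path(out_dir, "har_genes.txt"))
  }

  roles <- table(carto$role)
  summary <- list(
    interactome = list(genes = length(net$genes), links = nrow(net$edges)),
    parameters = list(alpha = config$alpha, epsilon = config$epsilon,
                      n_perm = config$n_perm, r_min = config$r_min,
                      r_max = r_max, step = config$step,
                      high_threshold = config$high_threshold,
                      medium_threshold = config$medium_threshold,
                      top_k_medium = config$top_k_medium,
                      ora_fdr = config$ora_fdr, band_fdr = config$band_fdr,
                      window_bp = config$window_bp,
                      rng_seed = config$rng_seed),
    top_network = list(
      genes = length(sel$genes), links = nrow(sel$edges), r = sel$r,
      modularity_Q = part$Q, n_communities = length(unique(part$membership)),
      n_components = comp$no,
      component_sizes = sort(as.integer(comp$csize), decreasing = TRUE),
      n_sig = sel$n_sig, p_resampling = sel$p_resampling,
      p_disease_enrichment = sel$p_disease_enrichment,
      hubs = lapply(split(carto$gene, carto$role)[
        intersect(c("R5", "R6", "R7"), names(roles))], as.list)),
    enrichment = list(
      n_pathways_tested = if (is.null(ora)) NA else nrow(ora),
      n_pathways_significant = if (is.null(ora)) NA else
        sum(ora$fdr < config$ora_fdr),
      n_meta_pathways = if (is.null(meta)) NA else
        length(unique(meta$clusters)),
      meta_threshold = if (is.null(meta)) NA else meta$threshold,
      meta_Q = if (is.null(meta)) NA else meta$Q),
    genomics = list(
      n_bands_significant = if (is.null(bands)) NA else
        sum(bands$significant),
      n_linkage_pairs = if (is.null(linkage)) NA else nrow(linkage),
      har_counts = if (is.null(harrep)) NA else as.list(harrep$counts))
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, na = "null", digits = NA,
                       pretty = TRUE)
  invisible(list(interactome = net, diffusion = result, extraction = ext,
                 partition = part, cartography = carto, ora = ora,
                 meta = meta, bands = bands, linkage = linkage, har = harrep,
                 summary = summary))
}

#' Overlap report between two gene lists
#'
#' `k = |A intersect B|`, the percentage of A covered (round half up, as
#' percentages are conventionally reported), and the upper-tail
#' hypergeometric p-value of the overlap against the universe.
#'
#' @param list_a,list_b Character vectors (A is the reference for the
#'   percentage).
#' @param universe Background gene set; both lists are intersected with it
#'   (with a message when genes fall outside).
#' @return List with `k`, `percent`, `p`, `n_a`, `n_b`, `n_universe`.
#' @export
overlap_report <- function(list_a, list_b, universe) {
  universe <- unique(as.character(universe))
  a <- unique(as.character(list_a)); b <- unique(as.character(list_b))
  out_a <- setdiff(a, universe); out_b <- setdiff(b, universe)
  if (length(out_a) || length(out_b)) {
    message(sprintf("overlap_report: %d/%d genes outside the universe dropped",
                    length(out_a), length(out_b)))
  }
  a <- intersect(a, universe); b <- intersect(b, universe)
  if (!length(a)) stopf("list A is empty after intersection with the universe")
  k <- length(intersect(a, b))
  list(k = k, percent = round_half_up(100 * k / length(a)),
       p = hypergeom_pvalue(k, length(b), length(a), length(universe)),
       n_a = length(a), n_b = length(b), n_universe = length(universe))
}
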