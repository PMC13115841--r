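#' Benchmark configuration
#'
#' Defaults describe the study conditions the pipeline is validated under: a
#' 500-gene scale-free background (Barabasi--Albert, m = 3) with a planted
#' 40-gene module wired at intra-module edge probability 0.25 (well above the
#' background density), half of the module genes used as seeds plus a 3%
#' scatter of background seeds, a 30-gene disease list overlapping the module
#' by 15, a 50-gene DEG list overlapping by 10, 20 pathways derived from the
#' graph's communities, 5 chromosomes x 4 bands with half the module genes
#' clustered on one band, and a 30-gene HAR list overlapping the module by 8.
#'
#' @param n_genes Number of genes.
#' @param background `"ba"` (Barabasi--Albert) or `"er"` (Erdos--Renyi).
#' @param ba_m Edges per new vertex for the BA model.
#' @param er_p Edge probability for the ER model.
#' @param module_size,module_p Planted module size and intra-module edge
#'   probability.
#' @param seed_frac_module Fraction of module genes used as seeds.
#' @param seed_frac_background Fraction of background genes used as seeds.
#' @param disease_size,disease_module_overlap Disease list size and its
#'   overlap with the module.
#' @param deg_size,deg_module_overlap DEG list size and module overlap.
#' @param n_pathways,pathway_size_range,pathway_noise Pathway collection
#'   shape: count, size range, and the fraction of each pathway replaced by
#'   random genes.
#' @param n_chromosomes,bands_per_chrom Genome layout.
#' @param clustered_band_fraction Fraction of module genes placed on one band.
#' @param har_size,har_module_overlap HAR list size and module overlap.
#' @param frac_high_background Fraction of background edges given
#'   high-confidence scores (the rest get the medium band).
#' @param rng_seed RNG seed; the whole benchmark is a pure function of the
#'   config.
#' @return A validated `benchmark_config` list.
#' @export
benchmark_config <- function(n_genes = 500L, background = c("ba", "er"),
                             ba_m = 3L, er_p = 0.02,
                             module_size = 40L, module_p = 0.25,
                             seed_frac_module = 0.5,
                             seed_frac_background = 0.03,
                             disease_size = 30L, disease_module_overlap = 15L,
                             deg_size = 50L, deg_module_overlap = 10L,
                             n_pathways = 20L, pathway_size_range = c(5L, 40L),
                             pathway_noise = 0.2,
                             n_chromosomes = 5L, bands_per_chrom = 4L,
                             clustered_band_fraction = 0.5,
                             har_size = 30L, har_module_overlap = 8L,
                             frac_high_background = 0.6, rng_seed = 1L) {
  background <- match.arg(background)
  cfg <- list(n_genes = as.integer(n_genes), background = background,
              ba_m = as.integer(ba_m), er_p = er_p,
              module_size = as.integer(module_size), module_p = module_p,
              seed_frac_module = seed_frac_module,
              seed_frac_background = seed_frac_background,
              disease_size = as.integer(disease_size),
              disease_module_overlap = as.integer(disease_module_overlap),
              deg_size = as.integer(deg_size),
              deg_module_overlap = as.integer(deg_module_overlap),
              n_pathways = as.integer(n_pathways),
              pathway_size_range = as.integer(pathway_size_range),
              pathway_noise = pathway_noise,
              n_chromosomes = as.integer(n_chromosomes),
              bands_per_chrom = as.integer(bands_per_chrom),
              clustered_band_fraction = clustered_band_fraction,
              har_size = as.integer(har_size),
              har_module_overlap = as.integer(har_module_overlap),
              frac_high_background = frac_high_background,
              rng_seed = as.integer(rng_seed))
  probs <- c(cfg$module_p, cfg$er_p, cfg$seed_frac_module,
             cfg$seed_frac_background, cfg$pathway_noise,
             cfg$clustered_band_fraction, cfg$frac_high_background)
  if (any(probs < 0 | probs > 1)) stopf("probabilities must lie in [0, 1]")
  if (cfg$module_size >= cfg$n_genes) stopf("module_size must be < n_genes")
  if (cfg$disease_module_overlap > min(cfg$disease_size, cfg$module_size)) {
    stopf("disease_module_overlap exceeds disease or module size")
  }
  if (cfg$deg_module_overlap > min(cfg$deg_size, cfg$module_size)) {
    stopf("deg_module_overlap exceeds DEG or module size")
  }
  if (cfg$har_module_overlap > min(cfg$har_size, cfg$module_size)) {
    stopf("har_module_overlap exceeds HAR or module size")
  }
  if (cfg$disease_size > cfg$n_genes || cfg$har_size > cfg$n_genes ||
      cfg$deg_size > cfg$n_genes) {
    stopf("annotation set sizes must not exceed n_genes")
  }
  structure(cfg, class = "benchmark_config")
}

#' Generate a complete synthetic benchmark
#'
#' Emits every pipeline input with the statistical structure the analysis
#' assumes: a STRING-dialect links table (per-channel subscores, both edge
#' orientations, a text-mining channel that must be excluded), an
#' identifier-mapping table, seed/disease/DEG/HAR gene lists overlapping the
#' planted module as configured, a pathway GMT built from noisy copies of the
#' graph's communities, a gene locus table with one band loaded with module
#' genes, and the ground truth. Fully reproducible from `config$rng_seed`.
#'
#' @param config A [benchmark_config()].
#' @param dir Optional output directory; when given, all files are written
#'   there (links.txt, mapping.tsv, seeds.txt, disease.txt, deg.txt,
#'   pathways.gmt, loci.tsv, har.txt, truth.json) and paths returned in
#'   `$files`.
#' @param planted Internal: `FALSE` generates the matched null (no module
#'   wiring, uniform seeds, independent annotation lists).
#' @return List with `links`, `mapping`, `seeds`, `disease`, `deg`,
#'   `pathways`, `loci`, `har`, `truth`, `config` (and `files` if written).
#' @export
generate_benchmark <- function(config = benchmark_config(), dir = NULL,
                               planted = TRUE) {
  stopifnot(inherits(config, "benchmark_config"))
  cfg <- config
  out <- with_local_seed(cfg$rng_seed, {
    n <- cfg$n_genes
    genes <- sprintf("G%04d", seq_len(n))

    g0 <- if (cfg$background == "ba") {
      igraph::sample_pa(n, m = cfg$ba_m, directed = FALSE)
    } else {
      igraph::sample_gnp(n, cfg$er_p)
    }
    el <- igraph::as_edgelist(g0, names = FALSE)

    module_idx <- sort(sample.int(n, cfg$module_size))
    if (planted && cfg$module_size >= 2) {
      prs <- utils::combn(module_idx, 2)
      add <- stats::runif(ncol(prs)) < cfg$module_p
      el <- rbind(el, t(prs[, add, drop = FALSE]))
    }
    a <- pmin(el[, 1], el[, 2]); b <- pmax(el[, 1], el[, 2])
    keep <- !duplicated(cbind(a, b)) & a != b
    a <- a[keep]; b <- b[keep]

    in_module <- (a %in% module_idx) & (b %in% module_idx)
    high <- in_module | (stats::runif(length(a)) < cfg$frac_high_background)
    score <- integer(length(a))
    score[high] <- as.integer(round(stats::runif(sum(high), 700, 1000)))
    score[!high] <- as.integer(round(stats::runif(sum(!high), 400, 699)))

    n_seed_mod <- round(cfg$seed_frac_module * cfg$module_size)
    n_seed_bg <- round(cfg$seed_frac_background * (n - cfg$module_size))
    if (planted) {
      seeds_idx <- c(sample(module_idx, n_seed_mod),
                     sample(setdiff(seq_len(n), module_idx), n_seed_bg))
    } else {
      seeds_idx <- sample.int(n, n_seed_mod + n_seed_bg)
    }

    pick_with_overlap <- function(size, overlap) {
      if (planted) {
        c(sample(module_idx, overlap),
          sample(setdiff(seq_len(n), module_idx), size - overlap))
      } else {
        sample.int(n, size)
      }
    }
    disease_idx <- pick_with_overlap(cfg$disease_size, cfg$disease_module_overlap)
    deg_idx <- pick_with_overlap(cfg$deg_size, cfg$deg_module_overlap)
    har_idx <- pick_with_overlap(cfg$har_size, cfg$har_module_overlap)

    # pathways: noisy copies of community gene sets of the generated graph
    gg <- igraph::graph_from_edgelist(cbind(a, b), directed = FALSE)
    gg <- igraph::add_vertices(gg, max(0, n - igraph::vcount(gg)))
    comm <- igraph::membership(igraph::cluster_fast_greedy(
      igraph::simplify(gg), weights = NA))
    comm_sets <- split(seq_len(n), comm)
    comm_sets <- comm_sets[lengths(comm_sets) >= 3]
    pathways <- vector("list", cfg$n_pathways)
    pathway_comm <- integer(cfg$n_pathways)
    for (ip in seq_len(cfg$n_pathways)) {
      ci <- ((ip - 1L) %% length(comm_sets)) + 1L
      base <- comm_sets[[ci]]
      target <- sample(seq(cfg$pathway_size_range[1],
                           cfg$pathway_size_range[2]), 1)
      target <- max(3L, min(target, length(base), 200L))
      memb <- sample(base, target)
      n_noise <- min(round(cfg$pathway_noise * target), n - target)
      if (n_noise > 0) {
        memb <- c(memb[seq_len(target - n_noise)],
                  sample(setdiff(seq_len(n), memb), n_noise))
      }
      pathways[[ip]] <- sort(genes[memb])
      pathway_comm[ip] <- as.integer(names(comm_sets)[ci])
    }
    names(pathways) <- sprintf("PW%03d", seq_len(cfg$n_pathways))
    attr(pathways, "description") <- stats::setNames(
      sprintf("community %d copy", pathway_comm), names(pathways))

    # loci: bands are contiguous 10 Mb blocks; target band hosts the module
    n_bands <- cfg$n_chromosomes * cfg$bands_per_chrom
    band_labels <- paste0(rep(c("p", "q"), each = ceiling(cfg$bands_per_chrom / 2)),
                          rep(seq_len(ceiling(cfg$bands_per_chrom / 2)), 2) + 10L)
    band_labels <- band_labels[seq_len(cfg$bands_per_chrom)]
    band_of <- integer(n)
    n_clust <- round(cfg$clustered_band_fraction * cfg$module_size)
    clustered <- if (planted && n_clust > 0) sample(module_idx, n_clust) else integer()
    band_of[clustered] <- 1L
    rest <- setdiff(seq_len(n), clustered)
    band_of[rest] <- sample(2:n_bands, length(rest), replace = TRUE)
    chrom_of <- (band_of - 1L) %/% cfg$bands_per_chrom + 1L
    band_in_chrom <- (band_of - 1L) %% cfg$bands_per_chrom + 1L
    band_len <- 10e6
    start <- end <- numeric(n)
    for (bnd in seq_len(n_bands)) {
      ix <- which(band_of == bnd)
      if (!length(ix)) next
      offset <- (bnd - 1L) %% cfg$bands_per_chrom * band_len
      pos <- sort(sample.int(band_len - 2e5, length(ix)))
      width <- round(stats::runif(length(ix), 5e3, 1e5))
      start[ix] <- offset + pos
      end[ix] <- offset + pos + width
    }
    loci <- data.frame(gene = genes, chrom = paste0("chr", chrom_of),
                       start = as.integer(start), end = as.integer(end),
                       band = band_labels[band_in_chrom],
                       stringsAsFactors = FALSE)

    # STRING-dialect links with per-channel subscores, both orientations
    proteins <- sprintf("9606.ENSP%05d", seq_len(n))
    tm <- integer(length(a))
    has_tm <- stats::runif(length(a)) < 0.3
    tm[has_tm] <- as.integer(round(stats::runif(sum(has_tm), 100, 900)))
    prior <- 0.041
    sp_exp <- pmax(0, (score / 1000 - prior) / (1 - prior))
    sp_tm <- pmax(0, (tm / 1000 - prior) / (1 - prior))
    combined <- as.integer(round(1000 * ((1 - (1 - sp_exp) * (1 - sp_tm)) *
                                           (1 - prior) + prior)))
    one_way <- data.frame(
      protein1 = proteins[a], protein2 = proteins[b],
      neighborhood = 0L, fusion = 0L, cooccurence = 0L, coexpression = 0L,
      experiments = score, database = 0L, textmining = tm,
      combined_score = combined, stringsAsFactors = FALSE)
    other_way <- one_way
    other_way$protein1 <- one_way$protein2
    other_way$protein2 <- one_way$protein1
    links <- rbind(one_way, other_way)
    links <- links[order(links$protein1, links$protein2), ]
    rownames(links) <- NULL

    truth <- list(module = genes[sort(module_idx)],
                  seeds = genes[sort(seeds_idx)],
                  disease = genes[sort(disease_idx)],
                  deg = genes[sort(deg_idx)],
                  har = genes[sort(har_idx)],
                  enriched_band = if (planted && n_clust > 0) "chr1p11" else NA_character_,
                  pathway_to_community = stats::setNames(pathway_comm,
                                                         names(pathways)),
                  planted = planted)

    list(links = links,
         mapping = stats::setNames(genes, proteins),
         seeds = genes[sort(seeds_idx)], disease = genes[sort(disease_idx)],
         deg = genes[sort(deg_idx)], har = genes[sort(har_idx)],
         pathways = pathways, loci = loci, truth = truth, config = cfg)
  })
  if (!is.null(dir)) {
    out$files <- write_benchmark(out, dir)
  }
  out
}

#' @rdname generate_benchmark
#' @export
null_benchmark <- function(config = benchmark_config(background = "er"),
                           dir = NULL) {
  generate_benchmark(config, dir = dir, planted = FALSE)
}

write_benchmark <- function(bench, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(x) file.path(dir, x)
  utils::write.table(bench$links, fp("links.txt"), sep = " ", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(data.frame(protein = names(bench$mapping),
                                gene = unname(bench$mapping)),
                     fp("mapping.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  write_gene_list(bench$seeds, fp("seeds.txt"))
  write_gene_list(bench$disease, fp("disease.txt"))
  write_gene_list(bench$deg, fp("deg.txt"))
  write_gene_list(bench$har, fp("har.txt"))
  write_gmt(bench$pathways, fp("pathways.gmt"))
  write_loci(bench$loci, fp("loci.tsv"))
  truth <- bench$truth
  truth$pathway_to_community <- as.list(truth$pathway_to_community)
  jsonlite::write_json(truth, fp("truth.json"), auto_unbox = TRUE,
                       null = "null", na = "null")
  files <- c(links = fp("links.txt"), mapping = fp("mapping.tsv"),
             seeds = fp("seeds.txt"), disease = fp("disease.txt"),
             deg = fp("deg.txt"), har = fp("har.txt"),
             pathways = fp("pathways.gmt"), loci = fp("loci.tsv"),
             truth = fp("truth.json"))
  files
}
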