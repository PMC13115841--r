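#' Read a STRING-dialect protein links table
#'
#' Parses the whitespace/TSV `protein.links.full` dialect: a header row naming
#' the two node columns followed by one column per evidence channel and a
#' `combined_score` column, all scores integers on the 0--1000 scale. Gzipped
#' files are read transparently.
#'
#' @param path Path to the links file (optionally `.gz`).
#' @return A `data.frame` with columns `node_a`, `node_b`, one column per
#'   channel, and `combined_score`.
#' @export
read_string_links <- function(path) {
  if (!file.exists(path)) stopf("links file not found: %s", path)
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE)
  if (ncol(dt) < 3) stopf("links file %s: expected node columns plus scores", path)
  names(dt)[1:2] <- c("node_a", "node_b")
  score_cols <- setdiff(names(dt), c("node_a", "node_b"))
  for (cl in score_cols) {
    v <- dt[[cl]]
    if (!is.numeric(v)) stopf("links file %s: column '%s' is not numeric", path, cl)
    if (anyNA(v) || any(v < 0 | v > 1000)) {
      stopf("links file %s: column '%s' has scores outside [0, 1000]", path, cl)
    }
  }
  dt
}

#' Read a protein-to-gene identifier mapping
#'
#' Two-column whitespace/TSV file (protein id, gene id); lines starting with
#' `#` and a literal `protein<TAB>gene` header are skipped.
#'
#' @param path Path to the mapping file.
#' @return Named character vector: `mapping[protein] == gene`.
#' @export
read_id_mapping <- function(path) {
  if (!file.exists(path)) stopf("mapping file not found: %s", path)
  dt <- data.table::fread(path, header = FALSE, data.table = FALSE)
  if (ncol(dt) < 2) stopf("mapping file %s: expected two columns", path)
  a <- as.character(dt[[1]]); b <- as.character(dt[[2]])
  keep <- !startsWith(a, "#") & !(tolower(a) == "protein" & tolower(b) == "gene")
  stats::setNames(b[keep], a[keep])
}

#' Read a one-column gene list
#'
#' One identifier per line; blank lines and `#` comments ignored; duplicates
#' removed preserving first occurrence.
#'
#' @param path Path to the list file.
#' @return Character vector of gene identifiers.
#' @export
read_gene_list <- function(path) {
  if (!file.exists(path)) stopf("gene list not found: %s", path)
  x <- trimws(readLines(path, warn = FALSE))
  unique(x[nzchar(x) & !startsWith(x, "#")])
}

#' @rdname read_gene_list
#' @param genes Character vector to write.
#' @export
write_gene_list <- function(genes, path) {
  writeLines(as.character(genes), path)
  invisible(path)
}

#' Read and write GMT gene-set collections
#'
#' GMT is tab-separated: set name, description, then one gene per field.
#'
#' @param path Path to a `.gmt` file.
#' @return `read_gmt`: named list of character vectors, with a `description`
#'   attribute (named character vector).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stopf("GMT file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3)
  if (length(bad)) stopf("GMT file %s: line %d has fewer than 3 fields", path, bad[1])
  nm <- vapply(parts, `[[`, "", 1L)
  if (anyDuplicated(nm)) stopf("GMT file %s: duplicated set names", path)
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- nm
  attr(sets, "description") <- stats::setNames(vapply(parts, `[[`, "", 2L), nm)
  sets
}

#' @rdname read_gmt
#' @param sets Named list of character vectors (optionally with a
#'   `description` attribute).
#' @export
write_gmt <- function(sets, path) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  desc <- attr(sets, "description") %||% stats::setNames(names(sets), names(sets))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, desc[[nm]] %||% nm, sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read and write gene locus tables
#'
#' TSV with header columns `gene`, `chrom`, `start`, `end`, `band`;
#' coordinates are 1-based inclusive.
#'
#' @param path Path to the loci TSV.
#' @return A `data.frame` with those five columns.
#' @export
read_loci <- function(path) {
  if (!file.exists(path)) stopf("loci file not found: %s", path)
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE)
  need <- c("gene", "chrom", "start", "end", "band")
  if (!all(need %in% names(dt))) {
    stopf("loci file %s: needs columns %s", path, paste(need, collapse = ", "))
  }
  loci <- dt[, need]
  validate_loci(loci)
  loci
}

#' @rdname read_loci
#' @param loci Locus `data.frame` to write.
#' @export
write_loci <- function(loci, path) {
  validate_loci(loci)
  utils::write.table(loci[, c("gene", "chrom", "start", "end", "band")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

validate_loci <- function(loci) {
  stopifnot(is.data.frame(loci))
  if (any(loci$start > loci$end)) stopf("loci: start > end for some genes")
  invisible(loci)
}

#' Convert between 1-based loci tables and BED (0-based half-open)
#'
#' @param loci Locus table as from [read_loci()].
#' @return `loci_to_bed`: data.frame with `chrom`, `start`, `end`, `name`,
#'   `band`; `bed_to_loci`: a locus table.
#' @export
loci_to_bed <- function(loci) {
  validate_loci(loci)
  data.frame(chrom = loci$chrom, start = loci$start - 1L, end = loci$end,
             name = loci$gene, band = loci$band, stringsAsFactors = FALSE)
}

#' @rdname loci_to_bed
#' @param bed BED4+band data.frame (`chrom`, `start`, `end`, `name`, `band`).
#' @export
bed_to_loci <- function(bed) {
  loci <- data.frame(gene = bed$name, chrom = bed$chrom,
                     start = bed$start + 1L, end = bed$end,
                     band = bed$band, stringsAsFactors = FALSE)
  validate_loci(loci)
  loci
}

#' Write the canonical edge TSV (`gene_a<TAB>gene_b<TAB>score`)
#'
#' Pairs are order-normalized (`gene_a < gene_b`) and rows sorted
#' lexicographically so output is byte-stable.
#'
#' @param edges `data.frame` with `gene_a`, `gene_b`, `score`.
#' @param path Output path.
#' @export
write_edge_tsv <- function(edges, path) {
  a <- pmin(edges$gene_a, edges$gene_b)
  b <- pmax(edges$gene_a, edges$gene_b)
  df <- data.frame(gene_a = a, gene_b = b, score = edges$score,
                   stringsAsFactors = FALSE)
  df <- df[order(df$gene_a, df$gene_b), , drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_edge_tsv
#' @export
read_edge_tsv <- function(path) {
  if (!file.exists(path)) stopf("edge file not found: %s", path)
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE)
  need <- c("gene_a", "gene_b", "score")
  if (!all(need %in% names(dt))) stopf("edge file %s: needs columns %s", path,
                                       paste(need, collapse = ", "))
  dt[, need]
}
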