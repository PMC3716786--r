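# File formats: genotypes as TSV (header = site ids, one row per individual,
# first column the id, then codes 0/1/2/'.'), or VCF with diploid GT fields;
# graphs as a 2-column edge TSV plus a node list file so isolated nodes
# survive the round trip.

#' Read genotypes from TSV
#'
#' @param path file with a header row of site ids; each following row is an
#'   individual id followed by per-site codes `0` (hom-ref), `1` (het),
#'   `2` (hom-alt) or `.` (missing).
#' @return a `genotype_matrix`.
#' @export
read_genotypes_tsv <- function(path) {
  tab <- utils::read.delim(path, colClasses = "character", check.names = FALSE)
  ids <- tab[[1]]
  calls <- as.matrix(tab[, -1, drop = FALSE])
  calls[calls == "."] <- NA
  mode(calls) <- "integer"
  rownames(calls) <- ids
  genotype_matrix(calls)
}

#' Write genotypes to TSV
#'
#' @param m a `genotype_matrix`.
#' @param path output file.
#' @export
write_genotypes_tsv <- function(m, path) {
  x <- matrix(as.character(unclass(m)), nrow = nrow(m),
              dimnames = dimnames(m))
  x[is.na(x)] <- "."
  df <- data.frame(id = rownames(m), x, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read genotypes from VCF
#'
#' Extracts diploid GT fields and maps `0/0 -> 0`, `0/1` or `1/0 -> 1`,
#' `1/1 -> 2` and `./.` to missing (phased separators `|` are accepted).
#' Multi-allelic records are rejected: the model is bi-allelic SNPs only.
#'
#' @param path a VCF file (uncompressed or gzipped).
#' @return a `genotype_matrix` (individuals x sites).
#' @export
read_genotypes_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  alt <- vcfR::getALT(v)
  if (any(grepl(",", alt)))
    stop("multi-allelic sites are not supported")
  gt <- vcfR::extract.gt(v, element = "GT")
  map <- c("0/0" = 0L, "0|0" = 0L, "0/1" = 1L, "1/0" = 1L, "0|1" = 1L,
           "1|0" = 1L, "1/1" = 2L, "1|1" = 2L)
  known <- gt %in% c(names(map), "./.", ".|.", ".", NA)
  if (!all(known)) stop("unsupported GT value: ", gt[!known][1])
  calls <- matrix(map[gt], nrow = nrow(gt))
  sites <- vcfR::getID(v)
  if (any(is.na(sites) | duplicated(sites)))
    sites <- paste0(vcfR::getCHROM(v), ":", vcfR::getPOS(v))
  dimnames(calls) <- list(sites, colnames(gt))
  genotype_matrix(t(calls))
}

#' Write a graph as edge-list and node-list TSV
#'
#' @param g an igraph.
#' @param edge_path 2-column TSV of edges.
#' @param node_path 1-column TSV of all vertex names (keeps isolated nodes).
#' @export
write_graph_tsv <- function(g, edge_path, node_path = NULL) {
  el <- igraph::as_edgelist(g)
  utils::write.table(data.frame(from = el[, 1], to = el[, 2]), edge_path,
                     sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(node_path))
    utils::write.table(data.frame(node = igraph::V(g)$name), node_path,
                       sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(edge_path)
}

#' Read a graph from edge-list (and optional node-list) TSV
#'
#' @param edge_path 2-column TSV with a header row.
#' @param node_path optional node list TSV preserving isolated vertices.
#' @return an igraph.
#' @export
read_graph_tsv <- function(edge_path, node_path = NULL) {
  el <- utils::read.delim(edge_path, colClasses = "character")
  nodes <- if (!is.null(node_path))
    utils::read.delim(node_path, colClasses = "character")[[1]] else NULL
  as_simple_graph(as.matrix(el), nodes = nodes)
}
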