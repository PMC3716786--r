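# Genotype calls are coded as integers: 0 = homozygous reference (HOM0),
# 1 = heterozygous (HET), 2 = homozygous alternate (HOM1), NA = missing.
# With this coding two calls conflict iff |a - b| == 2 (opposite homozygotes),
# and a genotype is the site-wise sum of its two binary haplotypes.

#' Construct a genotype matrix
#'
#' @param calls integer matrix, individuals in rows (rownames = ids), sites
#'   in columns (colnames = site ids); values in `{0, 1, 2, NA}`.
#' @return an object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(calls) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (is.null(rownames(calls))) rownames(calls) <- paste0("g", seq_len(nrow(calls)))
  if (is.null(colnames(calls))) colnames(calls) <- paste0("s", seq_len(ncol(calls)))
  bad <- !(calls %in% c(0L, 1L, 2L, NA))
  if (any(bad)) stop("invalid genotype codes: ",
                     paste(unique(calls[bad]), collapse = ", "))
  if (anyDuplicated(rownames(calls))) stop("duplicate individual ids")
  if (anyDuplicated(colnames(calls))) stop("duplicate site ids")
  structure(calls, class = c("genotype_matrix", "matrix"))
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("Genotype matrix:", nrow(x), "individuals x", ncol(x), "sites;",
      sum(is.na(x)), "missing calls\n")
  invisible(x)
}

check_call <- function(a) {
  if (!all(a %in% c(0L, 1L, 2L, NA))) stop("unknown call code")
  as.integer(a)
}

#' Site-level consistency of two genotype calls
#'
#' Two calls at one site are consistent with haplotype sharing unless they
#' are opposite homozygotes. Heterozygous and missing calls are compatible
#' with anything (missing acts as a wildcard).
#'
#' @param a,b calls in `{0, 1, 2, NA}` (vectorised).
#' @return logical.
#' @export
site_consistent <- function(a, b) {
  a <- check_call(a); b <- check_call(b)
  if (length(a) != length(b)) stop("call vectors differ in length")
  out <- abs(a - b) != 2L
  out[is.na(out)] <- TRUE
  out
}

#' Genotype-level consistency
#'
#' `TRUE` iff the two call vectors are site-consistent everywhere, i.e. the
#' two individuals could share a haplotype.
#'
#' @param g1,g2 call vectors of equal length.
#' @return logical scalar.
#' @export
genotypes_consistent <- function(g1, g2) {
  all(site_consistent(g1, g2))
}

#' Number of incompatible sites between two genotypes
#'
#' Counts the sites where the two calls are opposite homozygotes. Zero iff
#' the genotypes are consistent; used as the insertion weight in the
#' edge-editing program (sites that must be miscalls for an edge to exist).
#'
#' @param g1,g2 call vectors of equal length.
#' @return non-negative integer.
#' @export
incompatibility_count <- function(g1, g2) {
  sum(!site_consistent(g1, g2))
}

#' Preprocess a genotype matrix
#'
#' Removes individuals with no heterozygous call (their single haplotype is
#' directly observable and the model assumes two distinct haplotypes per
#' individual) and collapses duplicate call vectors to one representative,
#' since the sharing graph cannot encode two individuals carrying the same
#' haplotype pair. The report preserves what was removed and why.
#'
#' @param m a `genotype_matrix`.
#' @return list with elements `matrix` (the cleaned `genotype_matrix`) and
#'   `report` (removed ids, duplicate groups, counts).
#' @export
preprocess_genotypes <- function(m) {
  stopifnot(inherits(m, "genotype_matrix"))
  het <- rowSums(m == 1L, na.rm = TRUE) > 0L
  hom_ids <- rownames(m)[!het]
  kept <- m[het, , drop = FALSE]
  key <- apply(kept, 1, function(r) paste(ifelse(is.na(r), ".", r), collapse = ""))
  first <- !duplicated(key)
  groups <- split(rownames(kept), key)
  dup_groups <- Filter(function(g) length(g) > 1L, groups)
  names(dup_groups) <- vapply(dup_groups, `[`, "", 1L)
  out <- kept[first, , drop = FALSE]
  if (nrow(out) == 0L) warning("no individuals left after preprocessing")
  # distinct homozygous call vectors each witness one directly observed haplotype
  hom_key <- if (length(hom_ids)) apply(m[hom_ids, , drop = FALSE], 1, paste, collapse = "") else character(0)
  list(matrix = genotype_matrix(out),
       report = list(removed_homozygous = hom_ids,
                     n_homozygous_haplotypes = length(unique(hom_key)),
                     duplicate_groups = dup_groups,
                     n_input = nrow(m), n_retained = nrow(out)))
}

#' Build the Clark-consistency graph
#'
#' One node per retained individual; an edge between two individuals iff
#' their genotypes are consistent with sharing a haplotype (no site with
#' opposite homozygotes). Isolated nodes are kept.
#'
#' @param m a preprocessed `genotype_matrix`.
#' @return an igraph with vertex names equal to individual ids.
#' @export
build_cc_graph <- function(m) {
  stopifnot(inherits(m, "genotype_matrix"))
  A0 <- (m == 0L); A0[is.na(A0)] <- FALSE
  A2 <- (m == 2L); A2[is.na(A2)] <- FALSE
  conf <- A0 %*% t(A2)
  conf <- conf + t(conf)
  adj <- conf == 0
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  g <- igraph::set_vertex_attr(g, "name", value = rownames(m))
  g
}
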