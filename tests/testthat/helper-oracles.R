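# Shared fixtures and independent oracles. Oracles stay brute-force and
# library-based (igraph line-graph construction, exhaustive subset search,
# exhaustive phasing enumeration) so they are independent of the code paths
# they check.

named_graph <- function(g) {
  igraph::V(g)$name <- as.character(seq_len(igraph::vcount(g)))
  g
}

rand_graph <- function(n, p) {
  named_graph(igraph::sample_gnp(n, p))
}

graph_from_pairs <- function(n, pairs) {
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  igraph::V(g)$name <- as.character(seq_len(n))
  if (length(pairs)) g <- igraph::add_edges(g, as.character(pairs))
  g
}

# forward line-graph construction via igraph (independent of reconstruct_root)
line_of <- function(g) {
  lg <- igraph::make_line_graph(g)
  named_graph(lg)
}

# exhaustive minimum edge deletions to reach a line graph (catalog test used
# as the recognizer; its agreement with Krausz is checked separately)
brute_min_edge_deletions <- function(g) {
  m <- igraph::ecount(g)
  if (is_line_graph(g)) return(0L)
  for (k in seq_len(m)) {
    for (del in utils::combn(m, k, simplify = FALSE)) {
      if (is_line_graph(igraph::delete_edges(g, del))) return(k)
    }
  }
  m
}

brute_min_node_deletions <- function(g) {
  n <- igraph::vcount(g)
  if (is_line_graph(g)) return(0L)
  for (k in seq_len(n)) {
    for (del in utils::combn(n, k, simplify = FALSE)) {
      if (is_line_graph(igraph::delete_vertices(g, del))) return(k)
    }
  }
  n
}

# exhaustive minimum number of haplotypes explaining a set of genotypes:
# enumerate every resolution of each genotype's heterozygous sites and count
# distinct haplotypes, minimising over the cartesian product. Tiny n only.
brute_min_phasing_haplotypes <- function(m) {
  resolve <- function(g) {
    het <- which(g == 1L)
    base1 <- ifelse(is.na(g), 0L, g %/% 2L)
    base2 <- base1
    if (!length(het)) return(list(rbind(base1, base2)))
    out <- list()
    for (mask in 0:(2^(length(het) - 1) - 1)) {
      bits <- as.integer(intToBits(mask))[seq_along(het)]
      h1 <- base1; h2 <- base2
      h1[het] <- bits; h2[het] <- 1L - bits
      out[[length(out) + 1L]] <- rbind(h1, h2)
    }
    out
  }
  opts <- lapply(seq_len(nrow(m)), function(i) resolve(unclass(m)[i, ]))
  best <- Inf
  rec <- function(i, haps) {
    if (length(haps) >= best) return()
    if (i > length(opts)) { best <<- min(best, length(haps)); return() }
    for (o in opts[[i]]) {
      key <- c(paste(o[1, ], collapse = ""), paste(o[2, ], collapse = ""))
      rec(i + 1L, union(haps, key))
    }
  }
  rec(1L, character(0))
  best
}

# small genotype matrix from explicit haplotype pairs
geno_from_haps <- function(haps, pairing) {
  calls <- t(vapply(pairing, function(p) haps[p[1], ] + haps[p[2], ],
                    numeric(ncol(haps))))
  rownames(calls) <- paste0("g", seq_along(pairing))
  genotype_matrix(calls)
}

glpsol_available <- function() nzchar(Sys.which("glpsol"))
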