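# The nine minimal non-line graphs (claw first). Shipped as a plain edge-list
# table under extdata; loaded once per session and cached.

.linehap_env <- new.env(parent = emptyenv())

#' The forbidden-subgraph catalog
#'
#' Returns the nine minimal graphs that cannot occur as induced subgraphs of
#' any line graph: the claw `K(1,3)` and eight further graphs on 5 or 6
#' vertices with at most 10 edges. Minimality means each one stops being
#' forbidden after deleting any single vertex. The catalog is shipped as a
#' packaged edge-list file and can be re-derived from first principles with
#' [derive_forbidden_catalog()].
#'
#' @return list of 9 igraphs, ordered with the claw first, then by vertex
#'   and edge count.
#' @export
forbidden_catalog <- function() {
  if (!is.null(.linehap_env$catalog)) return(.linehap_env$catalog)
  path <- system.file("extdata", "forbidden_catalog.tsv", package = "linehap")
  if (path == "") path <- file.path("inst", "extdata", "forbidden_catalog.tsv")
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  gs <- lapply(split(tab, tab$graph), function(d) {
    n <- max(c(d$from, d$to))
    g <- igraph::make_empty_graph(n = n, directed = FALSE)
    g <- igraph::set_vertex_attr(g, "name", value = as.character(seq_len(n)))
    igraph::add_edges(g, rbind(d$from, d$to))
  })
  gs <- gs[order(as.integer(names(gs)))]
  names(gs) <- NULL
  .linehap_env$catalog <- gs
  gs
}

#' Derive the forbidden catalog by exhaustive enumeration
#'
#' Enumerates all connected graphs on 4-6 vertices (up to isomorphism) and
#' keeps those that fail Krausz-partition recognition while every
#' single-vertex-deleted induced subgraph passes it. This is the independent
#' derivation of the shipped catalog; it takes a couple of minutes and is
#' used to regenerate the data file, not at run time.
#'
#' @param max_n largest vertex count to scan (6 suffices).
#' @return list of igraphs.
#' @export
derive_forbidden_catalog <- function(max_n = 6L) {
  krausz_line <- function(g) {
    for (cmp in igraph::decompose(g)) {
      if (ecount(cmp) == 0L) next
      if (is.null(krausz_partition(adj_logical(cmp),
                                   igraph::as_edgelist(cmp, names = FALSE))))
        return(FALSE)
    }
    TRUE
  }
  found <- list()
  seen <- character(0)
  for (n in 4:max_n) {
    pairs <- t(utils::combn(n, 2))
    np <- nrow(pairs)
    for (mask in seq_len(2^np) - 1L) {
      sel <- bitwAnd(bitwShiftR(mask, seq_len(np) - 1L), 1L) == 1L
      if (sum(sel) < 3L) next
      g <- igraph::make_empty_graph(n = n, directed = FALSE)
      g <- igraph::set_vertex_attr(g, "name", value = as.character(seq_len(n)))
      g <- igraph::add_edges(g, t(pairs[sel, , drop = FALSE]))
      if (!igraph::is_connected(g)) next
      if (krausz_line(g)) next
      minimal <- TRUE
      for (v in seq_len(n)) {
        if (!krausz_line(igraph::delete_vertices(g, v))) { minimal <- FALSE; break }
      }
      if (!minimal) next
      dup <- FALSE
      for (u in found) {
        if (vcount(u) == n && ecount(u) == sum(sel) && igraph::isomorphic(u, g)) {
          dup <- TRUE; break
        }
      }
      if (!dup) found[[length(found) + 1L]] <- g
    }
  }
  # order: claw first, then by (n, m)
  nn <- vapply(found, function(g) as.integer(vcount(g)), 1L)
  mm <- vapply(found, function(g) as.integer(ecount(g)), 1L)
  claw <- igraph::make_star(4, mode = "undirected")
  is_claw <- vapply(found, function(g) igraph::isomorphic(g, claw), logical(1))
  found[order(!is_claw, nn, mm)]
}

# write the catalog data file (used once to produce inst/extdata)
write_catalog_tsv <- function(gs, path) {
  rows <- do.call(rbind, lapply(seq_along(gs), function(i) {
    el <- igraph::as_edgelist(gs[[i]], names = FALSE)
    data.frame(graph = i, from = el[, 1], to = el[, 2])
  }))
  utils::write.table(rows, path, sep = "\t", row.names = FALSE, quote = FALSE)
}
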